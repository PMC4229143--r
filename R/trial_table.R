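#' Plot-level trial records
#'
#' A trial table is a long-format data.frame of plot-level observations from
#' a clonally replicated multi-environment trial, with columns
#' `genotype_id`, `population_id`, `year`, `field_id`, `block_id`, `trait`,
#' `value`. Each genotype belongs to exactly one source population, and each
#' (genotype, year, block) combination carries at most one record per trait.
#'
#' @param df data.frame with the columns above.
#' @return the validated data.frame, with class `trial_table` prepended.
#' @export
trial_table <- function(df) {
  need <- c("genotype_id", "population_id", "year", "field_id",
            "block_id", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "))
  df$year <- as.integer(df$year)
  df$value <- as.numeric(df$value)
  pop_map <- unique(df[, c("genotype_id", "population_id")])
  dup <- pop_map$genotype_id[duplicated(pop_map$genotype_id)]
  if (length(dup))
    stop("genotype(s) mapped to more than one population: ",
         paste(utils::head(dup, 5), collapse = ", "))
  key <- paste(df$genotype_id, df$year, df$block_id, df$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (genotype, year, block, trait) record(s)")
  class(df) <- c("trial_table", class(df))
  df
}

#' @rdname trial_table
#' @param path CSV path in the long dialect above.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  trial_table(data.table::fread(path, data.table = FALSE))
}

#' @rdname trial_table
#' @param t a `trial_table`
#' @export
write_trial_table <- function(t, path) {
  data.table::fwrite(as.data.frame(t), path)
  invisible(path)
}

#' Map from genotype to source population
#'
#' @param t a `trial_table`
#' @return named character vector, `genotype_id -> population_id`.
#' @export
population_map <- function(t) {
  u <- unique(as.data.frame(t)[, c("genotype_id", "population_id")])
  stats::setNames(as.character(u$population_id), u$genotype_id)
}
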