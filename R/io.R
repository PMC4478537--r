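# TSV/JSON writers. TSV: tab separated, '.' decimal, header row,
# generation column first. JSON: UTF-8 via jsonlite, scalars unboxed.

#' Write a trajectory as TSV
#'
#' Columns `generation`, `c1`, `c2`, `c3`, `mean_dev`, `mean_fitness`.
#'
#' @param run a result of [simulate_trajectory()] (class
#'   `"psm_trajectory"`).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_tsv <- function(run, path) {
  stopifnot(inherits(run, "psm_trajectory"))
  df <- run$trajectory[, c("generation", "c1", "c2", "c3", "mean_dev",
                           "mean_fitness")]
  write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-locus frequency snapshots as TSV
#'
#' Long format with columns `generation`, `locus_index`, `effect`,
#' `freq`, one row per recorded generation and locus.
#'
#' @inheritParams write_trajectory_tsv
#' @export
write_freq_snapshots_tsv <- function(run, path) {
  stopifnot(inherits(run, "psm_trajectory"))
  if (is.null(run$freq_snapshots))
    stop("run was simulated without `record_freqs = TRUE`")
  snaps <- run$freq_snapshots
  gens <- run$trajectory$generation
  ell <- ncol(snaps)
  df <- data.frame(generation = rep(gens, each = ell),
                   locus_index = rep(seq_len(ell), times = length(gens)),
                   effect = rep(run$state$effects, times = length(gens)),
                   freq = as.vector(t(snaps)))
  write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
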