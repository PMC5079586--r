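# Shared fixtures: the grouper life history used throughout, a typical
# logistic gear, and a CSV writer for reader tests.

grouper_lh <- function(...) bacalao_life_history(...)

gear <- function(sl50 = 39, sl95 = 46.7) selectivity_params(sl50, sl95)

write_records_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

photo_lengths_path <- function() {
  system.file("extdata", "historical_photo_lengths.csv", package = "lenstock")
}

indicator_summary_path <- function() {
  system.file("extdata", "indicator_summary.csv", package = "lenstock")
}
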