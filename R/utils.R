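# Internal helpers shared across modules.

#' @importFrom stats quantile rnorm rpois runif phyper setNames
#' @importFrom utils read.delim write.table
NULL

# Round half away from zero (base round() rounds half to even; published
# percentage tables use conventional half-up rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# sample() with the size-1 gotcha removed: sample_from(5L, 1) never expands to 1:5
sample_from <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
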