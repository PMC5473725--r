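`%||%` <- function(x, y) if (is.null(x)) y else x

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.valid_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# two-sided normal p from a z statistic, in log space for extreme tails
.z_to_log_p <- function(z) log(2) + pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.numeric(v) && v == round(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    sprintf("%.17g", as.numeric(v))
  }, character(1))
  out
}

# write a data frame as a deterministic tab-delimited table
.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- .fmt_num(df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
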