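# Internal helpers: condition classes, seeding, name canonicalisation.

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("traitrates_input_error", "traitrates_error")))
}

stop_numeric <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("traitrates_numeric_error", "traitrates_error")))
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulation helpers do not perturb user code.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_input("seed must be a single integer, got '%s'", paste(seed, collapse = ","))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Species labels from tree files and CSVs come from heterogeneous literature
# sources: match after trimming whitespace and unifying spaces/underscores.
canonical_labels <- function(x) {
  gsub("[ _]+", "_", trimws(as.character(x)))
}

# Cholesky factor (lower triangular) of a covariance matrix, with a
# domain-specific diagnosis when the matrix is singular because two tips sit
# at zero patristic distance.
chol_lower <- function(C, what = "phylogenetic covariance matrix") {
  fac <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(fac)) {
    if (!is.null(rownames(C)) && nrow(C) >= 2) {
      lab <- rownames(C)
      pairs <- character(0)
      for (i in seq_len(nrow(C) - 1L)) for (j in seq(i + 1L, nrow(C))) {
        d <- C[i, i] + C[j, j] - 2 * C[i, j]
        if (is.finite(d) && abs(d) < 1e-12) pairs <- c(pairs, paste0(lab[i], "/", lab[j]))
      }
      if (length(pairs))
        stop_numeric("%s is singular: taxa at zero patristic distance: %s",
                     what, paste(pairs, collapse = ", "))
    }
    stop_numeric("%s is not positive definite", what)
  }
  t(fac)
}

is_square_symmetric <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) &&
    max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

# p-values printed the way comparative-rate tables report them: two decimals,
# "<0.01" when that would display as 0.00, "<0.001" below that threshold.
format_p <- function(p, digits = 2) {
  out <- formatC(p, format = "f", digits = digits)
  zero <- formatC(0, format = "f", digits = digits)
  out[out == zero] <- "<0.01"
  out[p < 0.001] <- "<0.001"
  out
}
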