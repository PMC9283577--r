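## Internal helpers shared across modules.

# 95% CI multiplier fixed package-wide.
.Z95 <- 1.959964

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.complement <- function(x) unname(.COMPLEMENT[x])

.isPalindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer 'seed' is required", call. = FALSE)
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

# Two-sided normal p, clamped away from exactly 0 so p stays in (0, 1].
.pNorm2 <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)

.pT2 <- function(t, df) pmax(2 * stats::pt(-abs(t), df = df), .Machine$double.xmin)

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  invisible(x)
}

# Canonical empty variant table (sumstats dialect, in-memory form).
.emptyVariants <- function() {
  data.frame(snp = character(), chr = character(), pos = integer(),
             ea = character(), oa = character(), eaf = numeric(),
             beta = numeric(), se = numeric(), pval = numeric(),
             n = numeric(), stringsAsFactors = FALSE)
}

.emptyInstruments <- function() {
  data.frame(snp = character(), beta_exp = numeric(), se_exp = numeric(),
             beta_out = numeric(), se_out = numeric(), eaf_exp = numeric(),
             pval_exp = numeric(), n_exp = numeric(), n_out = numeric(),
             action = character(), stringsAsFactors = FALSE)
}
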