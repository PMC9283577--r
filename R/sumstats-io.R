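#' @include accessors.R
NULL

## On-disk dialect: tab-separated, UTF-8, one header row. Canonical column
## names: snp, chr, pos, ea, oa, eaf, beta, se, pval, n. A user-supplied
## column map handles other headers. LD matrices are TSV with variant IDs as
## both the first column and the header row.

.MANDATORY <- c("snp", "ea", "oa", "beta", "se", "pval")

#' Read a GWAS summary-statistics table
#'
#' Reads the tab-separated dialect (columns `snp`, `chr`, `pos`, `ea`, `oa`,
#' `eaf`, `beta`, `se`, `pval`, `n`; `columnMap` renames other headers).
#' Rows violating the record invariants — non-numeric or non-positive SE,
#' p-value outside (0, 1], indel or multi-allelic alleles, duplicate variant
#' IDs — are rejected, counted and logged in the returned object's metadata
#' rather than aborting the read. Alleles are upper-cased; `eaf` and `n` are
#' optional.
#'
#' @param path file path.
#' @param columnMap optional named character vector mapping canonical names
#'   to the file's header names, e.g. `c(snp = "rsid", pval = "p")`.
#' @param traitName,traitType trait label and type for the returned object.
#' @return a [SumStats-class] object; `mrMetadata(x)$rejections` is a
#'   data.frame (`row`, `snp`, `reason`) of rejected rows and
#'   `mrMetadata(x)$rowsIn` the raw row count.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("snp\tchr\tpos\tea\toa\teaf\tbeta\tse\tpval\tn",
#'              "rs1\t1\t100\ta\tg\t0.3\t0.12\t0.01\t1e-30\t20000"), tf)
#' readSumStats(tf, traitName = "FA")
readSumStats <- function(path, columnMap = NULL, traitName = "trait",
                         traitType = c("quantitative", "binary")) {
  traitType <- match.arg(traitType)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = FALSE,
                           fileEncoding = "UTF-8")
  if (!is.null(columnMap)) {
    for (canon in names(columnMap)) {
      hit <- match(columnMap[[canon]], names(raw))
      if (!is.na(hit)) names(raw)[hit] <- canon
    }
  }
  missing <- setdiff(.MANDATORY, names(raw))
  if (length(missing))
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (opt in c("chr", "pos", "eaf", "n"))
    if (is.null(raw[[opt]])) raw[[opt]] <- NA_character_

  n <- nrow(raw)
  num <- function(x) suppressWarnings(as.numeric(x))
  d <- data.frame(snp = raw$snp, chr = raw$chr, pos = num(raw$pos),
                  ea = toupper(raw$ea), oa = toupper(raw$oa),
                  eaf = num(raw$eaf), beta = num(raw$beta), se = num(raw$se),
                  pval = num(raw$pval), n = num(raw$n),
                  stringsAsFactors = FALSE)

  reason <- rep(NA_character_, n)
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(!d$ea %in% .BASES | !d$oa %in% .BASES, "non_snp_alleles")
  flag(d$ea == d$oa, "identical_alleles")
  flag(!is.finite(d$beta), "non_numeric_beta")
  flag(!is.finite(d$se), "non_numeric_se")
  flag(is.finite(d$se) & d$se <= 0, "non_positive_se")
  flag(!is.finite(d$pval), "non_numeric_pval")
  flag(is.finite(d$pval) & (d$pval <= 0 | d$pval > 1), "pval_out_of_range")
  flag(is.finite(d$pos) & d$pos < 1, "position_out_of_range")
  flag(is.finite(d$eaf) & (d$eaf < 0 | d$eaf > 1), "eaf_out_of_range")
  flag(duplicated(d$snp), "duplicate_variant_id")

  keep <- is.na(reason)
  rejections <- data.frame(row = which(!keep), snp = d$snp[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
  d <- d[keep, , drop = FALSE]
  d$pos <- as.integer(d$pos)
  rownames(d) <- NULL
  SumStats(d, traitName = traitName, traitType = traitType,
           metadata = list(rowsIn = n, rowsAccepted = sum(keep),
                           rejections = rejections, source = path))
}

#' Write a GWAS summary-statistics table
#'
#' Writes the canonical tab-separated dialect. Floats are serialized with 10
#' significant digits so that `readSumStats(writeSumStats(x))` reproduces
#' every field.
#'
#' @param x a [SumStats-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSumStats <- function(x, path) {
  stopifnot(is(x, "SumStats"))
  d <- variants(x)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.10g", v))
  out <- data.frame(snp = d$snp, chr = ifelse(is.na(d$chr), "NA", d$chr),
                    pos = ifelse(is.na(d$pos), "NA", as.character(d$pos)),
                    ea = d$ea, oa = d$oa, eaf = fmt(d$eaf), beta = fmt(d$beta),
                    se = fmt(d$se), pval = fmt(d$pval), n = fmt(d$n),
                    stringsAsFactors = FALSE)
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' Read a pairwise LD (r-squared) matrix
#'
#' Expects a tab-separated square table with variant IDs as both the first
#' column and the header row. Asymmetries up to 1e-6 are repaired by
#' averaging; larger ones are rejected, as are diagonal entries off 1 by
#' more than 1e-6 and entries outside \[0, 1\].
#'
#' @param path file path.
#' @return an [LdMatrix-class] object.
#' @export
readLdMatrix <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           fileEncoding = "UTF-8")
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[-1])
  rownames(m) <- ids
  if (nrow(m) != ncol(m))
    stop("LD matrix must be square", call. = FALSE)
  if (!identical(rownames(m), colnames(m)))
    stop("LD matrix row and column IDs must match", call. = FALSE)
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("LD matrix entries must be numeric", call. = FALSE)
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6)
    stop(sprintf("LD matrix asymmetric beyond tolerance (max |delta| = %g)",
                 asym), call. = FALSE)
  m <- (m + t(m)) / 2
  if (max(abs(diag(m) - 1)) > 1e-6)
    stop("LD matrix diagonal must be 1", call. = FALSE)
  diag(m) <- 1
  if (any(m < 0 | m > 1))
    stop("r-squared values must lie in [0, 1]", call. = FALSE)
  LdMatrix(m)
}

#' Write a pairwise LD matrix
#'
#' @param x an [LdMatrix-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLdMatrix <- function(x, path) {
  stopifnot(is(x, "LdMatrix"))
  m <- x@r2
  out <- cbind(snp = x@variantIds,
               as.data.frame(matrix(sprintf("%.10g", m), nrow = nrow(m),
                                    dimnames = dimnames(m))))
  names(out) <- c("snp", x@variantIds)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
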