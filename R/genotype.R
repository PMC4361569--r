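#' @keywords internal
"_PACKAGE"

# Allele universe: *1 (wild type), *2, *3 (reduced activity).
.ALLELES <- c("*1", "*2", "*3")

#' Canonical CYP2C9 genotype labels
#'
#' The six diploid genotypes formed from alleles \*1, \*2 and \*3, in
#' canonical order (allele indices non-decreasing): `*1/*1`, `*1/*2`,
#' `*1/*3`, `*2/*2`, `*2/*3`, `*3/*3`.
#'
#' @return Character vector of length 6.
#' @export
genotype_levels <- function() {
  idx <- which(upper.tri(diag(3), diag = TRUE), arr.ind = TRUE)
  lab <- apply(idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE], 1,
               function(ij) paste(.ALLELES[ij[1]], .ALLELES[ij[2]], sep = "/"))
  unname(lab)
}

#' Parse genotype labels
#'
#' Accepts labels such as `"*1/*3"`, `"CYP2C9*3/*1"` or `"1/3"` and returns
#' the canonical label with alleles in non-decreasing index order, so
#' `"*3/*1"` and `"*1/*3"` are the same genotype.
#'
#' @param x character vector of genotype labels.
#' @return Character vector of canonical labels (one of [genotype_levels()]).
#' @examples
#' parse_genotype(c("CYP2C9*3/*1", "*2/*2"))
#' @export
parse_genotype <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  out <- character(length(x))
  for (i in seq_along(x)) {
    raw <- x[i]
    if (is.na(raw) || !nzchar(trimws(raw))) {
      stop("missing genotype label at position ", i, call. = FALSE)
    }
    s <- gsub("CYP2C9", "", trimws(raw), fixed = TRUE)
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("malformed genotype label ", sQuote(raw),
           ": expected two '/'-separated alleles", call. = FALSE)
    }
    al <- sub("^\\*", "", trimws(parts))
    bad <- !(al %in% c("1", "2", "3"))
    if (any(bad)) {
      stop("unsupported allele ", sQuote(paste0("*", al[bad][1])),
           " in genotype label ", sQuote(raw),
           "; supported alleles are *1, *2, *3", call. = FALSE)
    }
    ij <- sort(as.integer(al))
    out[i] <- paste(.ALLELES[ij[1]], .ALLELES[ij[2]], sep = "/")
  }
  out
}

#' Allele copy counts for genotypes
#'
#' Expands genotype labels into the n x 3 matrix of allele copy numbers
#' that is the design matrix of the zero-intercept allele model. Every row
#' sums to 2 (a diploid carries two allele copies), which is why that model
#' has no intercept: the three columns are collinear with a constant.
#'
#' @param genotype character vector of genotype labels (any parseable form).
#' @return Integer matrix with columns `"*1"`, `"*2"`, `"*3"`.
#' @examples
#' allele_counts(c("*1/*2", "*3/*3"))
#' @export
allele_counts <- function(genotype) {
  g <- parse_genotype(genotype)
  m <- matrix(0L, nrow = length(g), ncol = 3L,
              dimnames = list(NULL, .ALLELES))
  al <- strsplit(g, "/", fixed = TRUE)
  for (i in seq_along(g)) {
    for (a in al[[i]]) m[i, a] <- m[i, a] + 1L
  }
  m
}

# TRUE for homozygous genotypes ("*k/*k")
.is_homozygous <- function(genotype) {
  al <- strsplit(parse_genotype(genotype), "/", fixed = TRUE)
  vapply(al, function(p) p[1] == p[2], logical(1))
}
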