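#' Paired DNA-site / bridge-RNA alignment
#'
#' Holds `n` aligned records, each pairing a DNA recognition-window top-strand
#' row (columns 1..14 by default) with a bridge RNA row over scaffold
#' columns. In the fixed-width toy dialect there are no gaps; gapped imports
#' mask gap-containing columns ([read_paired_alignment()]).
#'
#' @param dna Character matrix (n x p) over A/C/G/T, or vector of strings.
#' @param brna Character matrix (n x q) over A/C/G/U, or vector of strings.
#' @return A `PairedAlignment` object.
#' @export
paired_alignment <- function(dna, brna) {
  to_mat <- function(x, alphabet, what) {
    if (is.character(x) && is.null(dim(x))) {
      if (length(unique(nchar(x))) != 1L)
        stop(what, " rows must all have equal length", call. = FALSE)
      x <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    }
    x[] <- toupper(x)
    bad <- setdiff(unique(as.vector(x)), alphabet)
    if (length(bad))
      stop(what, " contains invalid characters: ",
           paste(bad, collapse = ", "), call. = FALSE)
    x
  }
  dna <- to_mat(dna, DNA_BASES, "DNA block")
  brna <- to_mat(brna, RNA_BASES, "bRNA block")
  if (nrow(dna) != nrow(brna))
    stop("DNA and bRNA blocks must have the same number of records",
         call. = FALSE)
  if (nrow(dna) < 2L)
    stop("at least 2 records are required for any statistic", call. = FALSE)
  structure(list(dna = dna, brna = brna, n = nrow(dna)),
            class = "PairedAlignment")
}

#' @export
print.PairedAlignment <- function(x, ...) {
  cat("PairedAlignment: ", x$n, " records, DNA columns ", ncol(x$dna),
      ", bRNA columns ", ncol(x$brna), "\n", sep = "")
  invisible(x)
}

# column-wise mutual information (nats) between every DNA column and every
# bRNA column; plug-in estimator on the joint 4x4 table.
mutual_information_matrix <- function(dna_codes, brna_codes, n) {
  p <- ncol(dna_codes); q <- ncol(brna_codes)
  mi <- matrix(0, p, q)
  logn <- log(n)
  for (i in seq_len(p)) {
    xi <- dna_codes[, i]
    for (j in seq_len(q)) {
      joint <- tabulate(xi + 4L * (brna_codes[, j] - 1L), nbins = 16L)
      nz <- joint > 0L
      jx <- tabulate(xi, nbins = 4L)
      jy <- tabulate(brna_codes[, j], nbins = 4L)
      px <- jx[((which(nz) - 1L) %% 4L) + 1L]
      py <- jy[((which(nz) - 1L) %/% 4L) + 1L]
      jj <- joint[nz]
      mi[i, j] <- sum(jj * (log(jj) + logn - log(px) - log(py))) / n
    }
  }
  mi
}

#' Raw covariation matrix
#'
#' Mutual information between each DNA-window column and each bridge-RNA
#' column, with the average-product correction (APC) applied and the result
#' floored at zero. This is the in-package covariation statistic standing
#' behind the signed scale; the scale construction itself (normalisation and
#' concordance sign, [signed_scores()]) is the part of the analysis with a
#' defined end state.
#'
#' @param a A `PairedAlignment`.
#' @return Numeric matrix `C[i, j]` (DNA columns x bRNA columns), all
#'   entries `>= 0`. A fully monomorphic alignment gives an all-zero matrix
#'   with a warning.
#' @export
covariation_matrix <- function(a) {
  stopifnot(inherits(a, "PairedAlignment"))
  dc <- matrix(match(a$dna, DNA_BASES), nrow = a$n)
  bc <- matrix(match(a$brna, RNA_BASES), nrow = a$n)
  mono <- function(m) all(apply(m, 2, function(col) length(unique(col)) == 1L))
  if (mono(dc) && mono(bc)) {
    warning("alignment is fully monomorphic; covariation is identically zero",
            call. = FALSE)
    return(matrix(0, ncol(dc), ncol(bc)))
  }
  mi <- mutual_information_matrix(dc, bc, a$n)
  mbar <- mean(mi)
  apc <- if (mbar > 0) outer(rowMeans(mi), colMeans(mi)) / mbar else 0
  pmax(mi - apc, 0)
}

#' Signed, normalized covariation scores
#'
#' The covariation matrix is normalized by its maximum (an all-zero matrix
#' stays zero) and each entry is multiplied by the sign of a base-pairing
#' concordance score, yielding a scale from -1 (top-strand base pairing) to
#' +1 (bottom-strand base pairing). For DNA column `i` and bRNA column `j`,
#' `f_bottom(i, j)` is the fraction of records whose bRNA base at `j` is the
#' RNA transliteration of the top-strand base at `i` (a guide that pairs the
#' bottom strand carries the top strand's transliteration), and
#' `f_top(i, j)` the fraction whose bRNA base is the RNA complement of the
#' top-strand base (pairing the top strand directly). The sign is
#' `sign(f_bottom - f_top)` (zero when the two modes are balanced).
#'
#' @param a A `PairedAlignment`.
#' @return A `CovariationResult`: `raw`, `normalized` (in \[0, 1\]),
#'   `f_bottom`, `f_top`, `signed` (in \[-1, +1\]).
#' @examples
#' a <- simulate_alignment(200, planted = list(list(dna_col = 5,
#'   brna_col = 81, mode = "bottom", error_rate = 0)), seed = 7)
#' signed_scores(a)$signed[5, 81]  # +1
#' @export
signed_scores <- function(a) {
  stopifnot(inherits(a, "PairedAlignment"))
  raw <- covariation_matrix(a)
  m <- max(raw)
  normalized <- if (m > 0) raw / m else raw
  p <- ncol(a$dna); q <- ncol(a$brna)
  translit <- dna_to_rna(a$dna)        # bottom-strand pairing signature
  rnacomp <- rna_pairing_base(a$dna)   # top-strand pairing signature
  f_bottom <- matrix(0, p, q)
  f_top <- matrix(0, p, q)
  for (i in seq_len(p)) {
    ti <- translit[, i]; ci <- rnacomp[, i]
    f_bottom[i, ] <- colMeans(a$brna == ti)
    f_top[i, ] <- colMeans(a$brna == ci)
  }
  structure(list(raw = raw, normalized = normalized,
                 f_bottom = f_bottom, f_top = f_top,
                 signed = normalized * sign(f_bottom - f_top)),
            class = "CovariationResult")
}

#' Simulate a paired alignment with planted covarying columns
#'
#' Synthetic stand-in for orthologue alignments: unplanted columns are
#' i.i.d. uniform over the four bases; each planted bRNA column follows its
#' DNA column in the requested concordance mode with probability
#' `1 - error_rate` (else uniform). `"bottom"` mode writes the RNA
#' transliteration of the DNA top-strand base (the bottom-strand-pairing
#' signature); `"top"` writes its RNA complement.
#'
#' @param n Number of records (>= 2).
#' @param planted List of plantings, each a list with `dna_col`, `brna_col`,
#'   `mode` (`"bottom"` or `"top"`) and `error_rate` in \[0, 1).
#' @param seed Integer seed; identical seeds give byte-identical alignments.
#' @param n_dna,n_brna Column counts (defaults: the 14-position window and
#'   the 177-position scaffold).
#' @return A `PairedAlignment`; the plantings are attached as
#'   `attr(, "planted")`.
#' @export
simulate_alignment <- function(n, planted = list(), seed,
                               n_dna = 14L, n_brna = 177L) {
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  set.seed(seed)
  dna <- matrix(sample(DNA_BASES, n * n_dna, replace = TRUE), n, n_dna)
  brna <- matrix(sample(RNA_BASES, n * n_brna, replace = TRUE), n, n_brna)
  for (pl in planted) {
    er <- pl$error_rate %||% 0
    if (er < 0 || er >= 1) stop("error_rate must be in [0, 1)", call. = FALSE)
    mode_fun <- switch(pl$mode, bottom = dna_to_rna, top = rna_pairing_base,
                       stop("mode must be 'bottom' or 'top'", call. = FALSE))
    col <- mode_fun(dna[, pl$dna_col])
    noisy <- stats::runif(n) < er
    col[noisy] <- sample(RNA_BASES, sum(noisy), replace = TRUE)
    brna[, pl$brna_col] <- col
  }
  a <- paired_alignment(dna, brna)
  attr(a, "planted") <- planted
  a
}

#' Import a paired alignment from two aligned FASTA files
#'
#' The two files must contain the same number of records in the same order
#' (record-order pairing). Columns containing a gap character (`-` or `.`)
#' in any record are masked (dropped) from the corresponding block.
#'
#' @param dna_path Aligned FASTA of DNA window rows.
#' @param brna_path Aligned FASTA of bridge RNA rows.
#' @return A `PairedAlignment`.
#' @export
read_paired_alignment <- function(dna_path, brna_path) {
  read_block <- function(path) {
    set <- Biostrings::readBStringSet(path)
    m <- do.call(rbind, strsplit(toupper(as.character(set)), "", fixed = TRUE))
    gap <- apply(m, 2, function(col) any(col %in% c("-", ".")))
    if (any(gap))
      message("masked ", sum(gap), " gap-containing columns from ", path)
    m[, !gap, drop = FALSE]
  }
  dna <- read_block(dna_path)
  brna <- read_block(brna_path)
  brna[] <- chartr("T", "U", brna)
  paired_alignment(dna, brna)
}

#' Export a signed covariation matrix as TSV
#'
#' @param res A `CovariationResult`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_signed_scores <- function(res, path) {
  stopifnot(inherits(res, "CovariationResult"))
  m <- res$signed
  df <- data.frame(dna_col = as.integer(row(m)),
                   brna_col = as.integer(col(m)),
                   signed_score = as.numeric(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
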