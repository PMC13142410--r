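#' Barcode scheme for dual-plate combinatorial indexing
#'
#' A barcode scheme describes the two 8x12 Tn5 adapter plates and the nanowell
#' index whitelists used by a dual-transposase co-occupancy experiment. The
#' first plate carries s5 barcodes 1-8 and s7 barcodes 1-12; the second plate
#' carries s5 barcodes 9-16 and s7 barcodes 13-24. Because the two s5 sets (and
#' the two s7 sets) are read at the same position of the same index read, each
#' combined whitelist must be unambiguous: all sequences unique and pairwise
#' Hamming distance greater than `2 * max_mismatch`.
#'
#' Index-read layout is configuration, not convention: `i1_layout` and
#' `i2_layout` give the 1-based offset and length of each barcode component
#' within index read 1 (s7 + p7 well) and index read 2 (s5 + p5 well).
#'
#' @param s5,s7 Character vectors of 16 and 24 adapter barcode sequences
#'   (indices 1-16 and 1-24; the first 8 / 12 belong to plate A).
#' @param p5_wells,p7_wells Character vectors of nanowell index sequences.
#' @param max_mismatch Maximum Hamming distance tolerated when matching an
#'   observed barcode against a whitelist (default 1).
#' @param i1_layout,i2_layout Named lists `list(<component> = c(offset, length))`
#'   locating each barcode within its index read.
#' @return An object of class `barcode_scheme`.
#' @seealso [make_barcode_scheme()] to generate a valid synthetic scheme,
#'   [read_barcode_scheme()] / [write_barcode_scheme()] for JSON round trips.
#' @export
barcode_scheme <- function(s5, s7, p5_wells, p7_wells, max_mismatch = 1L,
                           i1_layout = NULL, i2_layout = NULL) {
  s5 <- toupper(as.character(s5)); s7 <- toupper(as.character(s7))
  p5_wells <- toupper(as.character(p5_wells)); p7_wells <- toupper(as.character(p7_wells))
  if (length(s5) != 16L) stop("need exactly 16 s5 barcodes (8 per plate)")
  if (length(s7) != 24L) stop("need exactly 24 s7 barcodes (12 per plate)")
  bc_len <- unique(nchar(c(s5, s7)))
  if (length(unique(nchar(s5))) != 1L || length(unique(nchar(s7))) != 1L)
    stop("barcodes within a whitelist must share one length")
  wl5 <- unique(nchar(p5_wells)); wl7 <- unique(nchar(p7_wells))
  if (length(wl5) != 1L || length(wl7) != 1L)
    stop("well barcodes within a whitelist must share one length")
  if (is.null(i1_layout))
    i1_layout <- list(s7 = c(1L, nchar(s7[1])), p7 = c(nchar(s7[1]) + 1L, wl7))
  if (is.null(i2_layout))
    i2_layout <- list(s5 = c(1L, nchar(s5[1])), p5 = c(nchar(s5[1]) + 1L, wl5))
  scheme <- structure(list(
    s5 = s5, s7 = s7, p5_wells = p5_wells, p7_wells = p7_wells,
    max_mismatch = as.integer(max_mismatch),
    i1_layout = lapply(i1_layout, as.integer),
    i2_layout = lapply(i2_layout, as.integer)), class = "barcode_scheme")
  validate_scheme(scheme)
  scheme
}

#' @export
print.barcode_scheme <- function(x, ...) {
  cat("barcode_scheme: dual 8x12 Tn5 plates\n")
  cat("  s5 whitelist: 16 x", nchar(x$s5[1]), "bp;  s7 whitelist: 24 x",
      nchar(x$s7[1]), "bp\n")
  cat("  nanowell p5/p7:", length(x$p5_wells), "x", nchar(x$p5_wells[1]),
      "bp /", length(x$p7_wells), "x", nchar(x$p7_wells[1]), "bp\n")
  cat("  max mismatch:", x$max_mismatch, "\n")
  invisible(x)
}

# every combined whitelist read at one position must stay unambiguous at the
# configured mismatch tolerance: pairwise Hamming distance > 2 * max_mismatch
validate_scheme <- function(scheme) {
  check <- function(wl, what) {
    if (anyDuplicated(wl)) stop("duplicate sequences in ", what, " whitelist")
    d <- min_pairwise_hamming(wl)
    if (d <= 2L * scheme$max_mismatch)
      stop(sprintf("%s whitelist min pairwise Hamming distance %d <= 2*max_mismatch (%d)",
                   what, d, 2L * scheme$max_mismatch))
  }
  check(scheme$s5, "s5"); check(scheme$s7, "s7")
  check(scheme$p5_wells, "p5"); check(scheme$p7_wells, "p7")
  invisible(TRUE)
}

min_pairwise_hamming <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  if (n < 2L) return(nchar(seqs[1]))
  best <- nchar(seqs[1])
  for (i in seq_len(n - 1L)) {
    d <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                   matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
    best <- min(best, d)
  }
  as.integer(best)
}

#' Generate a synthetic, valid barcode scheme
#'
#' Draws random whitelists (rejection sampling) satisfying the pairwise
#' Hamming-distance requirement of [barcode_scheme()]. Deterministic for a
#' given seed, so simulated experiments and their demultiplexing are fully
#' reproducible.
#'
#' @param seed Integer seed.
#' @param bc_len Adapter barcode length in bp (default 8).
#' @param well_len Nanowell index length in bp (default 8).
#' @param n_wells Number of nanowell indices per side (default 72).
#' @param max_mismatch Matching tolerance stored in the scheme.
#' @return A `barcode_scheme`.
#' @export
make_barcode_scheme <- function(seed = 1L, bc_len = 8L, well_len = 8L,
                                n_wells = 72L, max_mismatch = 1L) {
  set.seed(seed)
  min_d <- 2L * max_mismatch + 1L
  draw <- function(n, len) {
    kept <- character(0)
    mat <- NULL
    while (length(kept) < n) {
      cand <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      if (is.null(mat) || all(rowSums(mat != matrix(cand, nrow(mat), len,
                                                    byrow = TRUE)) >= min_d)) {
        kept <- c(kept, paste(cand, collapse = ""))
        mat <- rbind(mat, cand)
      }
    }
    kept
  }
  barcode_scheme(s5 = draw(16L, bc_len), s7 = draw(24L, bc_len),
                 p5_wells = draw(n_wells, well_len),
                 p7_wells = draw(n_wells, well_len),
                 max_mismatch = max_mismatch)
}

#' Read or write a barcode scheme as JSON
#'
#' @param path File path.
#' @return `read_barcode_scheme()` returns a validated `barcode_scheme`;
#'   `write_barcode_scheme()` returns `path` invisibly.
#' @export
read_barcode_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  barcode_scheme(s5 = x$s5, s7 = x$s7, p5_wells = x$p5_wells,
                 p7_wells = x$p7_wells, max_mismatch = x$max_mismatch,
                 i1_layout = x$i1_layout, i2_layout = x$i2_layout)
}

#' @rdname read_barcode_scheme
#' @param scheme A `barcode_scheme`.
#' @export
write_barcode_scheme <- function(scheme, path) {
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
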