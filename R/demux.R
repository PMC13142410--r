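#' Match an observed barcode against a whitelist
#'
#' Returns the index of the unique whitelist sequence within Hamming distance
#' `max_mismatch` of the observed sequence, or `NA` when nothing is close
#' enough or when two or more whitelist entries tie at the minimal distance
#' (an ambiguous call is never guessed).
#'
#' @param observed A single barcode sequence.
#' @param whitelist Ordered character vector of same-length sequences.
#' @param max_mismatch Maximum tolerated Hamming distance.
#' @return Integer whitelist index, or `NA_integer_`.
#' @export
match_barcode <- function(observed, whitelist, max_mismatch = 1L) {
  match_barcodes(observed, whitelist, max_mismatch)[1]
}

#' @rdname match_barcode
#' @details `match_barcodes()` is the vectorized form used by
#'   [demultiplex()]: one observed sequence per read.
#' @export
match_barcodes <- function(observed, whitelist, max_mismatch = 1L) {
  len <- nchar(whitelist[1])
  if (any(nchar(whitelist) != len))
    stop("whitelist sequences differ in length")
  if (any(nchar(observed) != len))
    stop("observed barcode length differs from whitelist length ", len)
  n <- length(observed)
  obs <- matrix(unlist(strsplit(observed, ""), use.names = FALSE),
                nrow = n, byrow = TRUE)
  D <- matrix(0L, n, length(whitelist))
  for (w in seq_along(whitelist)) {
    wm <- matrix(strsplit(whitelist[w], "")[[1]], n, len, byrow = TRUE)
    D[, w] <- as.integer(rowSums(obs != wm))
  }
  best <- D[, 1]
  for (w in seq_len(ncol(D))[-1]) best <- pmin(best, D[, w])
  hit <- max.col(-D, ties.method = "first")
  ties <- rowSums(D == best) > 1L
  hit[best > max_mismatch | ties] <- NA_integer_
  hit
}

#' Assign a read to its occupancy stream from its adapter barcode indices
#'
#' Reads whose s5 and s7 barcodes come from the same Tn5 plate are
#' mono-occupancy reads for that plate's target; mixed combinations evidence
#' both targets on the same molecule and form the two co-occupancy streams:
#' s5 1-8 with s7 1-12 is `target1`, s5 9-16 with s7 13-24 is `target2`,
#' s5 1-8 with s7 13-24 is `co1`, and s5 9-16 with s7 1-12 is `co2`.
#'
#' @param s5_index Integer vector in 1-16.
#' @param s7_index Integer vector in 1-24.
#' @return Character vector over `c("target1","target2","co1","co2")`.
#' @export
assign_stream <- function(s5_index, s7_index) {
  s5_index <- as.integer(s5_index); s7_index <- as.integer(s7_index)
  if (any(is.na(s5_index)) || any(s5_index < 1L | s5_index > 16L))
    stop("s5 index out of range 1-16")
  if (any(is.na(s7_index)) || any(s7_index < 1L | s7_index > 24L))
    stop("s7 index out of range 1-24")
  a5 <- s5_index <= 8L
  a7 <- s7_index <= 12L
  out <- character(length(s5_index))
  out[a5 & a7] <- "target1"
  out[!a5 & !a7] <- "target2"
  out[a5 & !a7] <- "co1"
  out[!a5 & a7] <- "co2"
  out
}

#' Map adapter barcode indices to the tagmentation plate well
#'
#' The four stream-defining barcode combinations of one physical well all
#' collapse to the same plate coordinate, so the cell barcode can be rewritten
#' as a well ID: rows A-H correspond to s5 ranks 1-8 on either plate
#' (s5 9-16 map to the same rows), columns 1-12 to s7 ranks on either plate.
#'
#' @inheritParams assign_stream
#' @return Character plate coordinates such as `"C7"`.
#' @export
well_id <- function(s5_index, s7_index) {
  s5_index <- as.integer(s5_index); s7_index <- as.integer(s7_index)
  if (any(is.na(s5_index)) || any(s5_index < 1L | s5_index > 16L))
    stop("s5 index out of range 1-16")
  if (any(is.na(s7_index)) || any(s7_index < 1L | s7_index > 24L))
    stop("s7 index out of range 1-24")
  row <- ifelse(s5_index <= 8L, s5_index, s5_index - 8L)
  col <- ifelse(s7_index <= 12L, s7_index, s7_index - 12L)
  paste0(LETTERS[row], col)
}

#' Build the rewritten cell barcode
#'
#' `well + p5 + p7`: identical for all four streams originating from one cell.
#' @param well Character well IDs from [well_id()].
#' @param p5_index,p7_index Nanowell whitelist indices.
#' @return Character cell barcodes such as `"C7+12+34"`.
#' @export
cell_barcode <- function(well, p5_index, p7_index) {
  paste(well, as.integer(p5_index), as.integer(p7_index), sep = "+")
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

write_fastq <- function(df, path) {
  dna <- Biostrings::DNAStringSet(df$seq)
  names(dna) <- df$id
  Biostrings::writeXStringSet(dna, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(df$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

extract_component <- function(seqs, layout, name) {
  off <- layout[[name]][1]; len <- layout[[name]][2]
  substr(seqs, off, off + len - 1L)
}

#' Demultiplex combinatorially indexed reads into occupancy streams
#'
#' Routes every read pair into one of four streams (`target1`, `target2`,
#' `co1`, `co2`) from the combination of its two Tn5 adapter barcodes, rewrites
#' the cell barcode as `well + p5 + p7` in the read header, and reports
#' per-stream and per-well counts. Keeping the two co-occupancy streams apart
#' preserves which paired end corresponds to each target protein; concatenating
#' them recovers the combined co-occupancy set used by most downstream steps.
#'
#' @param r1,r2 Paths to the genomic read FASTQ files (gzip transparent).
#' @param i1,i2 Paths to the index-read FASTQ files carrying the s7+p7 and
#'   s5+p5 barcodes, laid out as described by the scheme.
#' @param scheme A [barcode_scheme()].
#' @param out_dir Output directory; when `NULL` nothing is written and only
#'   the assignment table is returned.
#' @param emit_unassigned Also write reads whose barcodes failed to match.
#' @param gzip Compress outputs.
#' @return An object of class `demux_result`: list with `assignments`
#'   (per-read data.frame: stream, well, p5/p7 indices, cell barcode),
#'   `summary` (per-stream counts), `well_counts`, and output `files`.
#' @export
demultiplex <- function(r1, r2, i1, i2, scheme, out_dir = NULL,
                        emit_unassigned = FALSE, gzip = FALSE) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  R1 <- read_fastq(r1); R2 <- read_fastq(r2)
  I1 <- read_fastq(i1); I2 <- read_fastq(i2)
  n <- nrow(R1)
  sizes <- c(nrow(R2), nrow(I1), nrow(I2))
  if (any(sizes != n))
    stop(sprintf("FASTQ record counts differ (R1=%d R2=%d I1=%d I2=%d): truncated input near record %d",
                 n, sizes[1], sizes[2], sizes[3], min(c(n, sizes)) + 1L))
  key <- function(ids) sub("[ /].*$", "", ids)
  k1 <- key(R1$id)
  for (other in list(key(R2$id), key(I1$id), key(I2$id))) {
    bad <- which(k1 != other)
    if (length(bad))
      stop("FASTQ files desynchronized at record ", bad[1])
  }

  s7_obs <- extract_component(I1$seq, scheme$i1_layout, "s7")
  p7_obs <- extract_component(I1$seq, scheme$i1_layout, "p7")
  s5_obs <- extract_component(I2$seq, scheme$i2_layout, "s5")
  p5_obs <- extract_component(I2$seq, scheme$i2_layout, "p5")
  s5i <- match_barcodes(s5_obs, scheme$s5, scheme$max_mismatch)
  s7i <- match_barcodes(s7_obs, scheme$s7, scheme$max_mismatch)
  p5i <- match_barcodes(p5_obs, scheme$p5_wells, scheme$max_mismatch)
  p7i <- match_barcodes(p7_obs, scheme$p7_wells, scheme$max_mismatch)

  ok <- !(is.na(s5i) | is.na(s7i) | is.na(p5i) | is.na(p7i))
  stream <- rep("unassigned", n)
  well <- rep(NA_character_, n)
  cb <- rep(NA_character_, n)
  if (any(ok)) {
    stream[ok] <- assign_stream(s5i[ok], s7i[ok])
    well[ok] <- well_id(s5i[ok], s7i[ok])
    cb[ok] <- cell_barcode(well[ok], p5i[ok], p7i[ok])
  }
  assignments <- data.frame(read = k1, stream = stream, well = well,
                            s5 = s5i, s7 = s7i, p5 = p5i, p7 = p7i,
                            cell_barcode = cb, stringsAsFactors = FALSE)
  streams <- c("target1", "target2", "co1", "co2", "unassigned")
  summary <- data.frame(stream = streams,
                        count = as.integer(table(factor(stream, streams))))
  well_counts <- as.data.frame(table(well = well[ok], stream = stream[ok]),
                               stringsAsFactors = FALSE)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    emit <- if (emit_unassigned) streams else setdiff(streams, "unassigned")
    for (s in emit) {
      sel <- which(stream == s)
      hdr <- if (s == "unassigned") k1[sel] else sprintf("%s:%d", cb[sel], sel)
      f1 <- file.path(out_dir, paste0(s, "_R1", ext))
      f2 <- file.path(out_dir, paste0(s, "_R2", ext))
      write_fastq(data.frame(id = hdr, seq = R1$seq[sel], qual = R1$qual[sel]), f1)
      write_fastq(data.frame(id = hdr, seq = R2$seq[sel], qual = R2$qual[sel]), f2)
      files <- c(files, f1, f2)
    }
    utils::write.table(summary, file.path(out_dir, "demux_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(well_counts, file.path(out_dir, "well_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(assignments = assignments, summary = summary,
                 well_counts = well_counts, files = files),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  n <- sum(x$summary$count)
  cat("demux_result:", n, "read pairs\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-10s %8d (%.2f%%)\n", x$summary$stream[i],
                x$summary$count[i], 100 * x$summary$count[i] / max(n, 1L)))
  invisible(x)
}
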