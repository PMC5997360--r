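# PWM promoter scanning: count candidate Ebox/RRE/Dbox elements in promoter
# windows at a relative-score threshold, producing the (n1, n2, n3)
# exponents of the CCG model.
#
# Scoring: log2-odds against a uniform background (0.25 per base) with a
# total pseudocount of 0.8 distributed by background; relative score
# (S - Smin)/(Smax - Smin) in [0, 1]; both strands scanned; windows
# containing N are skipped; overlapping hits each counted.

DNA_BASES <- c("A", "C", "G", "T")

#' Read position frequency matrices in JASPAR text format
#'
#' Accepts both the bracketed dialect (`A  [ 3  0 ... ]`) and bare
#' four-row count blocks, each preceded by a `>id name` header.  Rows may
#' be labeled in any order; unlabeled rows are taken as A, C, G, T.
#' Raw counts with unequal column sums are accepted and normalized per
#' column.
#'
#' @param path file path.
#' @param pseudocount total pseudocount added per column, distributed by
#'   the background composition (default 0.8).
#' @param background base composition used for the log-odds (default
#'   uniform).
#' @return a single `pwm` object if the file holds one record, else a
#'   named list of `pwm` objects.
#' @export
read_pfm <- function(path, pseudocount = 0.8,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty PFM file: ", path)
  heads <- grep("^>", lines)
  if (!length(heads)) {
    heads <- 1L
    lines <- c(">motif", lines)
  }
  bounds <- c(heads, length(lines) + 1L)
  records <- lapply(seq_along(heads), function(i) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    header <- sub("^>\\s*", "", lines[bounds[i]])
    parts <- strsplit(header, "\\s+")[[1]]
    id <- parts[1]
    name <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else id
    if (length(block) != 4)
      stop("PFM record '", id, "' has ", length(block),
           " matrix rows; expected 4")
    labels <- toupper(sub("^([ACGTacgt])\\s.*", "\\1", block))
    labeled <- labels %in% DNA_BASES & nchar(labels) == 1
    rows <- lapply(seq_along(block), function(k) {
      txt <- block[k]
      if (labeled[k]) txt <- sub("^[ACGTacgt]", "", txt)
      txt <- gsub("\\[|\\]", " ", txt)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(txt),
                                                   "\\s+")[[1]]))
      if (any(is.na(vals)))
        stop("malformed PFM row (line ", which(lines == block[k])[1],
             ") in record '", id, "'")
      vals
    })
    L <- unique(vapply(rows, length, integer(1)))
    if (length(L) != 1)
      stop("PFM record '", id, "' has rows of unequal length")
    counts <- do.call(rbind, rows)
    rownames(counts) <- if (all(labeled)) labels else DNA_BASES
    counts <- counts[DNA_BASES, , drop = FALSE]
    new_pwm(id = id, name = name, counts = counts,
            pseudocount = pseudocount, background = background)
  })
  names(records) <- vapply(records, function(r) r$id, character(1))
  if (length(records) == 1) records[[1]] else records
}

#' Construct a PWM object from a count (or frequency) matrix
#'
#' @param id,name identifiers.
#' @param counts 4 x L non-negative matrix, rows A, C, G, T.
#' @param pseudocount,background see [read_pfm()].
#' @return object of class `pwm` with the derived log2-odds matrix and its
#'   achievable score range.
#' @export
new_pwm <- function(id, name = id, counts, pseudocount = 0.8,
                    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4 || ncol(counts) < 4)
    stop("PWM needs a 4 x L matrix with L >= 4")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("PWM columns must be finite and non-negative")
  rownames(counts) <- DNA_BASES
  bg <- background[DNA_BASES] / sum(background)
  freq <- sweep(counts + pseudocount * bg, 2,
                colSums(counts) + pseudocount, "/")
  freq[freq < .Machine$double.eps] <- .Machine$double.eps
  lods <- log2(freq / bg)
  structure(list(id = id, name = name, counts = counts, lods = lods,
                 min_score = sum(apply(lods, 2, min)),
                 max_score = sum(apply(lods, 2, max)),
                 consensus = paste(DNA_BASES[apply(lods, 2, which.max)],
                                   collapse = ""),
                 length = ncol(counts)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s): length %d, consensus %s, score range [%.2f, %.2f] bits\n",
              x$id, x$name, x$length, x$consensus, x$min_score, x$max_score))
  invisible(x)
}

# encode a DNA string to integer codes 1..4 (N and others -> NA)
encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  match(chars, DNA_BASES)
}

revcomp <- function(seq) {
  chartr("ACGTacgtN", "TGCAtgcaN", paste(rev(strsplit(seq, "")[[1]]),
                                         collapse = ""))
}

#' Relative PWM score of a single subsequence
#'
#' `(S - Smin) / (Smax - Smin)` where S is the log-odds sum; the minus
#' strand scores the reverse complement of the subsequence.
#'
#' @param pwm `pwm` object.
#' @param subseq character string of length `pwm$length` (no ambiguity
#'   codes).
#' @param strand `"+"` or `"-"`.
#' @return score in `[0, 1]`.
#' @export
relative_score <- function(pwm, subseq, strand = "+") {
  stopifnot(inherits(pwm, "pwm"))
  if (nchar(subseq) != pwm$length)
    stop("subsequence length ", nchar(subseq), " != PWM length ",
         pwm$length)
  if (strand == "-") subseq <- revcomp(subseq)
  codes <- encode_dna(subseq)
  if (any(is.na(codes))) stop("ambiguous base in subsequence")
  s <- sum(pwm$lods[cbind(codes, seq_len(pwm$length))])
  (s - pwm$min_score) / (pwm$max_score - pwm$min_score)
}

#' Construct a promoter region
#'
#' The scan window convention is -10 kb to +5 kb around the transcription
#' start site (15 kb total); shorter sequences are accepted.
#'
#' @param gene gene identifier.
#' @param seq DNA sequence (A/C/G/T/N), length <= 15000.
#' @param strand strand of the gene (recorded, not used by the scan).
#' @return list of class `promoter_region`.
#' @export
promoter_region <- function(gene, seq, strand = "+") {
  seq <- toupper(seq)
  if (nchar(seq) > 15000)
    stop("promoter region longer than the 15 kb window")
  if (grepl("[^ACGTN]", seq))
    stop("promoter sequence may contain only A, C, G, T, N")
  structure(list(gene = gene, seq = seq, strand = strand,
                 length = nchar(seq)),
            class = "promoter_region")
}

# score every offset of coded sequence against a lods matrix; NA where the
# window contains an ambiguous base
score_all_offsets <- function(codes, lods) {
  L <- ncol(lods)
  n <- length(codes)
  if (n < L) return(numeric(0))
  nwin <- n - L + 1L
  s <- numeric(nwin)
  for (j in seq_len(L)) s <- s + lods[, j][codes[j:(nwin + j - 1L)]]
  s
}

#' Scan a promoter region with one PWM
#'
#' Exhaustively scores every offset on both strands and reports hits with
#' relative score at or above the threshold.  Windows containing N are
#' skipped.  Overlapping hits each count.  Coordinates are reported
#' 1-based inclusive.
#'
#' @param region `promoter_region` (or plain character sequence).
#' @param pwm `pwm` object.
#' @param threshold relative-score threshold in `[0, 1]` (default 0.85).
#' @param both_strands scan the reverse strand as well (default TRUE).
#' @return data.frame of class `motif_hits`: gene, motif, start, end,
#'   strand, rel_score.
#' @export
pwm_scan <- function(region, pwm, threshold = 0.85, both_strands = TRUE) {
  if (is.character(region)) region <- promoter_region("region", region)
  stopifnot(inherits(region, "promoter_region"), inherits(pwm, "pwm"))
  L <- pwm$length
  codes <- encode_dna(region$seq)
  empty <- data.frame(gene = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), rel_score = numeric(0),
                      stringsAsFactors = FALSE)
  if (region$length < L) {
    warning("region '", region$gene, "' shorter than the motif; no hits")
    class(empty) <- c("motif_hits", "data.frame")
    return(empty)
  }
  rng <- pwm$max_score - pwm$min_score
  rel <- function(s) (s - pwm$min_score) / rng
  res <- list()
  fwd <- rel(score_all_offsets(codes, pwm$lods))
  keep <- which(!is.na(fwd) & fwd >= threshold)
  if (length(keep))
    res[["+"]] <- data.frame(gene = region$gene, motif = pwm$id,
                             start = keep, end = keep + L - 1L,
                             strand = "+", rel_score = fwd[keep],
                             stringsAsFactors = FALSE)
  if (both_strands) {
    # minus strand: score the reverse complement of each window, i.e. scan
    # with the reverse-complemented matrix at the same forward offsets
    rc_lods <- pwm$lods[4:1, L:1, drop = FALSE]
    rownames(rc_lods) <- DNA_BASES
    bwd <- rel(score_all_offsets(codes, rc_lods))
    keep <- which(!is.na(bwd) & bwd >= threshold)
    if (length(keep))
      res[["-"]] <- data.frame(gene = region$gene, motif = pwm$id,
                               start = keep, end = keep + L - 1L,
                               strand = "-", rel_score = bwd[keep],
                               stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, c(res, make.row.names = FALSE))
    else empty
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Count Ebox, RRE and Dbox elements in a promoter region
#'
#' Three scans; the hit counts are the (n1, n2, n3) exponents of the CCG
#' model, with full hit provenance retained.
#'
#' @param region `promoter_region`.
#' @param pwm_ebox,pwm_rre,pwm_dbox `pwm` objects for the three motif
#'   classes.
#' @param threshold relative-score threshold (default 0.85).
#' @return list of class `element_counts`: `n1`, `n2`, `n3`, `hits`
#'   (combined `motif_hits`), `gene`.
#' @export
count_elements <- function(region, pwm_ebox, pwm_rre, pwm_dbox,
                           threshold = 0.85) {
  h1 <- pwm_scan(region, pwm_ebox, threshold)
  h2 <- pwm_scan(region, pwm_rre, threshold)
  h3 <- pwm_scan(region, pwm_dbox, threshold)
  hits <- rbind(h1, h2, h3)
  hits$class <- rep(c("Ebox", "RRE", "Dbox"),
                    c(nrow(h1), nrow(h2), nrow(h3)))
  structure(list(gene = region$gene, n1 = nrow(h1), n2 = nrow(h2),
                 n3 = nrow(h3), hits = hits, threshold = threshold),
            class = "element_counts")
}

#' @export
print.element_counts <- function(x, ...) {
  cat(sprintf("%s: n1 (Ebox) = %d, n2 (RRE) = %d, n3 (Dbox) = %d @ threshold %.2f\n",
              x$gene, x$n1, x$n2, x$n3, x$threshold))
  invisible(x)
}

#' Bundled stand-in PWMs for the three motif classes
#'
#' Synthetic example matrices (Ebox/BMAL1-like, RRE/ROR-like,
#' Dbox/DBP-like) shipped for tests and demonstrations.  They are
#' constructed stand-ins, not database matrices.
#'
#' @return named list of `pwm` objects: `ebox`, `rre`, `dbox`.
#' @export
example_pwms <- function() {
  dir <- system.file("extdata", package = "clockdde")
  list(ebox = read_pfm(file.path(dir, "ebox_bmal1_synthetic.pfm")),
       rre = read_pfm(file.path(dir, "rre_ror_synthetic.pfm")),
       dbox = read_pfm(file.path(dir, "dbox_dbp_synthetic.pfm")))
}

#' Write motif hits in BED-like format
#'
#' Columns: seq_id, start (0-based), end (half-open), motif_id,
#' round(rel_score * 1000), strand.
#'
#' @param hits `motif_hits`.
#' @param path output path.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$gene, hits$start - 1L, hits$end, hits$motif,
                    as.integer(round(hits$rel_score * 1000)), hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
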