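# Central 20-mer of the sense SRE strand, positions -10..+10 (no zero).
# Reconstructed from the stated 7-bp inverted-repeat arms GATGTCC/GGACATC
# and the central 6-nt A/T run; flanks beyond +/-10 are not available here.
.sre_core20 <- "GATGTCCATATTAGGACATC"

#' Watson-Crick complement lookup
#' @noRd
.wc_complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Construct an oligonucleotide sequence with field-style position labels
#'
#' Positions follow the convention used for partially palindromic repeats:
#' labels run ..., -2, -1, 1, 2, ... with no zero, so the inversion centre
#' lies between positions -1 and 1.
#'
#' @param bases character vector of single bases (A/C/G/T) or a single
#'   string, 5' to 3'.
#' @param positions integer position labels, strictly increasing, no zero.
#'   Default: symmetric labels \code{-N/2..-1, 1..N/2} for even length,
#'   otherwise \code{1..N}.
#' @param name sample name.
#' @return an object of class \code{oligo_sequence} with fields
#'   \code{name}, \code{bases}, \code{positions}, \code{N}.
#' @export
oligo_sequence <- function(bases, positions = NULL, name = "oligo") {
  if (length(bases) == 1 && nchar(bases[1]) != 1)
    bases <- strsplit(bases, "")[[1]]
  bases <- toupper(bases)
  if (length(bases) < 1) stop("empty sequence")
  bad <- setdiff(unique(bases), c("A", "C", "G", "T"))
  if (length(bad))
    stop("invalid bases: ", paste(bad, collapse = ", "))
  n <- length(bases)
  if (is.null(positions)) {
    positions <- if (n %% 2 == 0) c(seq(-n / 2, -1), seq(1, n / 2)) else seq_len(n)
  }
  positions <- as.integer(positions)
  if (length(positions) != n) stop("positions must match sequence length")
  if (any(positions == 0L)) stop("position 0 is not allowed")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  structure(list(name = name, bases = bases, positions = positions, N = n),
            class = "oligo_sequence")
}

#' @export
print.oligo_sequence <- function(x, ...) {
  cat(sprintf("<oligo_sequence> %s: 5'-%s-3' (N = %d, positions %d..%d)\n",
              x$name, paste(x$bases, collapse = ""), x$N,
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' Convert a symmetric-numbering position label to an array index
#'
#' For a symmetric oligomer of even length N with labels -N/2..-1,1..N/2,
#' index = position + N/2 for negative labels and position + N/2 - 1 for
#' positive ones (there is no label zero).
#'
#' @param seq an \code{oligo_sequence}.
#' @param position integer position label(s).
#' @return 1-based index into \code{seq$bases}.
#' @export
position_to_index <- function(seq, position) {
  idx <- match(as.integer(position), seq$positions)
  if (anyNA(idx)) stop("position not present in sequence")
  idx
}

#' Convert an array index to the position label
#' @param seq an \code{oligo_sequence}.
#' @param index 1-based index.
#' @return integer position label.
#' @export
index_to_position <- function(seq, index) {
  if (any(index < 1 | index > seq$N)) stop("index out of range")
  seq$positions[index]
}

#' Build a central sense-strand SRE segment
#'
#' Returns the central \code{N}-mer of the sense SRE strand, symmetric about
#' the loop region, with position labels \code{-N/2..-1, 1..N/2}.  Only the
#' central 20 nucleotides (positions -10..+10) are reconstructable from the
#' inverted-repeat arms and the A/T core; the flanks required for N = 28 or
#' 36 are not available, and those lengths raise an error.
#'
#' @param N even segment length; supported: 12, 14, 16, 18, 20 (28 and 36
#'   are recognized but their flank sequence is unavailable).
#' @return an \code{oligo_sequence} named \code{SREseg<N>}.
#' @examples
#' seg16 <- build_sre_segment(16)
#' paste(seg16$bases, collapse = "")  # "TGTCCATATTAGGACA"
#' @export
build_sre_segment <- function(N) {
  supported <- c(12L, 14L, 16L, 18L, 20L, 28L, 36L)
  N <- as.integer(N)
  if (length(N) != 1 || !(N %in% supported))
    stop("unsupported N; supported lengths: ",
         paste(supported, collapse = ", "))
  if (N > 20L)
    stop("flank sequence unavailable for N = ", N,
         " (only positions -10..+10 are on record)")
  core <- strsplit(.sre_core20, "")[[1]]
  drop <- (20L - N) / 2L
  bases <- core[(drop + 1L):(20L - drop)]
  oligo_sequence(bases, name = sprintf("SREseg%d", N))
}

#' Enumerate the contiguous-stem hairpin fold of a sequence
#'
#' Pairs the outermost bases inward (position -k with +k in symmetric
#' numbering; first with last in array terms) for as long as the pairs are
#' Watson-Crick; pairing stops at the first non-WC encounter and all
#' remaining central bases form the loop.  Bulges and internal loops are
#' not considered.
#'
#' @param seq an \code{oligo_sequence}.
#' @param min_loop minimum loop length (>= 3).
#' @return a \code{fold_topology} with \code{kind = "hairpin"},
#'   \code{pairs} (data frame position_a, position_b, is_wc),
#'   \code{loop_positions}, \code{n_wc} and \code{molecularity = 1}.
#' @export
enumerate_hairpin_fold <- function(seq, min_loop = 3L) {
  stopifnot(inherits(seq, "oligo_sequence"))
  min_loop <- as.integer(min_loop)
  if (min_loop < 3L) stop("min_loop must be >= 3")
  if (seq$N < min_loop + 2L)
    stop("sequence shorter than min_loop + 2")
  b <- seq$bases
  n <- seq$N
  max_stem <- (n - min_loop) %/% 2L
  pa <- pb <- integer(0)
  k <- 0L
  while (k < max_stem) {
    i <- k + 1L
    j <- n - k
    if (.wc_complement[b[i]] != b[j]) break
    pa <- c(pa, seq$positions[i])
    pb <- c(pb, seq$positions[j])
    k <- k + 1L
  }
  loop_idx <- if (k < n - k) (k + 1L):(n - k) else integer(0)
  pairs <- data.frame(position_a = pa, position_b = pb,
                      is_wc = rep(TRUE, k))
  structure(list(kind = "hairpin", pairs = pairs,
                 loop_positions = seq$positions[loop_idx],
                 n_wc = k, molecularity = 1L, name = seq$name),
            class = "fold_topology")
}

#' Enumerate the antiparallel homoduplex fold of a sequence with itself
#'
#' Aligns two copies of the strand antiparallel, pairing index i of strand A
#' with index N+1-i of strand B; each of the N opposed pairs is flagged as
#' Watson-Crick or mismatch and \code{n_wc} counts the WC pairs.
#'
#' @param seq an \code{oligo_sequence}.
#' @return a \code{fold_topology} with \code{kind = "homoduplex"} and
#'   \code{molecularity = 2}.  \code{pairs$position_a} labels strand A
#'   positions, \code{pairs$position_b} the opposed strand B positions.
#' @export
enumerate_homoduplex_fold <- function(seq) {
  stopifnot(inherits(seq, "oligo_sequence"))
  b <- seq$bases
  n <- seq$N
  i <- seq_len(n)
  j <- n + 1L - i
  is_wc <- .wc_complement[b[i]] == b[j]
  pairs <- data.frame(position_a = seq$positions[i],
                      position_b = seq$positions[j],
                      is_wc = unname(is_wc))
  structure(list(kind = "homoduplex", pairs = pairs,
                 loop_positions = integer(0),
                 n_wc = sum(is_wc), molecularity = 2L, name = seq$name),
            class = "fold_topology")
}

#' @export
print.fold_topology <- function(x, ...) {
  cat(sprintf("<fold_topology> %s %s: %d WC pair(s), molecularity %d\n",
              x$name, x$kind, x$n_wc, x$molecularity))
  if (nrow(x$pairs)) {
    lab <- sprintf("(%+d,%+d)%s", x$pairs$position_a, x$pairs$position_b,
                   ifelse(x$pairs$is_wc, "", "*"))
    cat("  pairs (* = mismatch):", paste(lab, collapse = " "), "\n")
  }
  if (length(x$loop_positions))
    cat("  loop positions:", paste(x$loop_positions, collapse = " "), "\n")
  invisible(x)
}

#' Field-convention labels for base pairs of a fold
#'
#' Labels read base-of-plus-strand first, then its partner, with the
#' absolute position as subscript: e.g. the outermost stem pair of the
#' 16-mer segment is "AT_8" (A at +8 paired with T at -8).
#'
#' @param seq the \code{oligo_sequence} the fold was built from.
#' @param fold a \code{fold_topology}.
#' @return character vector, one label per pair.
#' @export
pair_labels <- function(seq, fold) {
  if (!nrow(fold$pairs)) return(character(0))
  a <- fold$pairs$position_a
  b <- fold$pairs$position_b
  plus <- pmax(a, b)
  minus <- pmin(a, b)
  sprintf("%s%s_%d%s",
          seq$bases[position_to_index(seq, plus)],
          seq$bases[position_to_index(seq, minus)],
          abs(plus),
          ifelse(fold$pairs$is_wc, "", "*"))
}

#' Molecular weight of a linear single-strand DNA oligonucleotide
#'
#' Oligo Calc convention for unmodified 5'-OH single strands:
#' nA*313.21 + nT*304.2 + nC*289.18 + nG*329.21 - 61.96 g/mol.
#' Alternative conventions (5'-phosphate, average isotopic tables) are not
#' used.
#'
#' @param seq an \code{oligo_sequence} or a base string.
#' @return mass in g/mol.
#' @examples
#' molecular_weight(build_sre_segment(16))  # 4880.26
#' @export
molecular_weight <- function(seq) {
  if (!inherits(seq, "oligo_sequence")) seq <- oligo_sequence(seq)
  masses <- c(A = 313.21, T = 304.2, C = 289.18, G = 329.21)
  sum(masses[seq$bases]) - 61.96
}

#' Read sequences from a FASTA file
#' @param path FASTA file path.
#' @return list of \code{oligo_sequence} (symmetric numbering for even
#'   lengths).
#' @export
read_fasta_oligos <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i)
    oligo_sequence(as.character(set[[i]]), name = names(set)[i]))
}

#' Write sequences to a FASTA file
#' @param seqs an \code{oligo_sequence} or list thereof.
#' @param path output path.
#' @export
write_fasta_oligos <- function(seqs, path) {
  if (inherits(seqs, "oligo_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(
    vapply(seqs, function(s) paste(s$bases, collapse = ""), character(1)))
  names(set) <- vapply(seqs, `[[`, character(1), "name")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a fold topology pair table as TSV
#' @param fold a \code{fold_topology}.
#' @param path output path.
#' @export
write_fold_report <- function(fold, path) {
  utils::write.table(fold$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
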