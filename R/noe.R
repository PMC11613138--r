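#' A NOESY cross-peak
#'
#' Atom labels are "residue atom" pairs such as \code{"C-4 H5"}: base
#' letter, signed position (no zero), atom name (H5, H6, H8, H1', H2,
#' M7, ...).
#'
#' @param atom_a,atom_b atom labels.
#' @param volume integrated cross-peak intensity (arbitrary units).
#' @param assignment_note free text.
#' @export
cross_peak <- function(atom_a, atom_b, volume, assignment_note = "") {
  structure(list(atom_a = atom_a, atom_b = atom_b,
                 volume = as.numeric(volume),
                 assignment_note = assignment_note),
            class = "cross_peak")
}

# split "C-4 H5" into residue/base/position/atom
.parse_atom <- function(label) {
  m <- regmatches(label,
                  regexec("^([ACGT])(-?[0-9]+)[ ]*([A-Z][A-Z0-9']*)$", label))[[1]]
  if (length(m) != 4)
    stop("cannot parse atom label: ", label)
  list(base = m[2], position = as.integer(m[3]), atom = m[4],
       residue = paste0(m[2], m[3]))
}

.is_ch5_h6_ref <- function(peak) {
  a <- tryCatch(.parse_atom(peak$atom_a), error = function(e) NULL)
  b <- tryCatch(.parse_atom(peak$atom_b), error = function(e) NULL)
  if (is.null(a) || is.null(b)) return(FALSE)
  a$base == "C" && b$base == "C" && a$position == b$position &&
    setequal(c(a$atom, b$atom), c("H5", "H6"))
}

#' Calibrate the NOE reference volume from cytosine H5-H6 peaks
#'
#' The intranucleotide cytosine H5-H6 distance is essentially fixed
#' (2.9 A); the arithmetic mean of all such cross-peak volumes serves as
#' the intensity reference for the sixth-power distance rule.
#'
#' @param peaks list of \code{cross_peak}.
#' @return reference volume I_ref (attribute \code{n_ref}: number of
#'   peaks averaged).
#' @export
calibrate_reference <- function(peaks) {
  if (inherits(peaks, "cross_peak")) peaks <- list(peaks)
  is_ref <- vapply(peaks, .is_ch5_h6_ref, logical(1))
  if (!any(is_ref)) stop("no CH5-H6 calibration peak")
  vols <- vapply(peaks[is_ref], `[[`, numeric(1), "volume")
  I_ref <- mean(vols)
  attr(I_ref, "n_ref") <- sum(is_ref)
  I_ref
}

#' Convert a cross-peak volume to an inter-proton distance
#'
#' Isolated-spin-pair approximation: d = d_ref (I_ref/I)^(1/6) with
#' d_ref = 2.9 A (the cytosine H5-H6 distance).  Methyl-group peaks
#' (atom M7) have their volume divided by 3 first (pseudo-atom
#' convention).  No spin-diffusion or relaxation-matrix correction is
#' applied.
#'
#' @param peak a \code{cross_peak} with positive volume.
#' @param I_ref reference volume from \code{\link{calibrate_reference}}.
#' @param d_ref reference distance, Angstrom.
#' @return a \code{distance_estimate} with fields pair, d, I, I_ref,
#'   d_ref.
#' @export
peak_to_distance <- function(peak, I_ref, d_ref = 2.9) {
  if (!is.finite(peak$volume) || peak$volume <= 0)
    stop("non-positive cross-peak volume for ",
         peak$atom_a, " x ", peak$atom_b)
  stopifnot(I_ref > 0)
  I <- peak$volume
  n_methyl <- sum(grepl("^M", c(tryCatch(.parse_atom(peak$atom_a)$atom,
                                         error = function(e) ""),
                                tryCatch(.parse_atom(peak$atom_b)$atom,
                                         error = function(e) ""))))
  I_eff <- I / 3^n_methyl
  d <- d_ref * (as.numeric(I_ref) / I_eff)^(1 / 6)
  structure(list(pair = c(peak$atom_a, peak$atom_b), d = d, I = I,
                 I_ref = as.numeric(I_ref), d_ref = d_ref),
            class = "distance_estimate")
}

#' Convert a peak list to distances
#'
#' Symmetric cross-peaks (the same atom pair above and below the
#' diagonal) are volume-averaged before conversion.
#'
#' @param peaks list of \code{cross_peak}.
#' @param I_ref reference volume; calibrated from the list itself when
#'   missing.
#' @param d_ref reference distance, Angstrom.
#' @return list of \code{distance_estimate}.
#' @export
peaks_to_distances <- function(peaks, I_ref = NULL, d_ref = 2.9) {
  if (inherits(peaks, "cross_peak")) peaks <- list(peaks)
  if (is.null(I_ref)) I_ref <- calibrate_reference(peaks)
  key <- vapply(peaks, function(p)
    paste(sort(c(p$atom_a, p$atom_b)), collapse = "|"), character(1))
  merged <- lapply(split(seq_along(peaks), key), function(idx) {
    p <- peaks[[idx[1]]]
    p$volume <- mean(vapply(peaks[idx], `[[`, numeric(1), "volume"))
    p
  })
  # keep first-appearance order
  merged <- merged[order(vapply(split(seq_along(peaks), key), min, 0L))]
  lapply(merged, peak_to_distance, I_ref = I_ref, d_ref = d_ref)
}

# B-DNA reference H1'-H6/H8 distances (Angstrom).  SYNTHETIC stand-in
# transcribed from standard fibre-model B-DNA geometry surveys, not from
# any specific deposited table: intranucleotide H1'-H6/H8 ~ 3.7 A (anti
# glycosidic conformation), sequential internucleotide H1'(i-1)-H6/H8(i)
# ~ 3.0 A.
#' Reference B-DNA H1'-H6/H8 distances
#'
#' Named vector with entries \code{intra} and \code{inter} (Angstrom).
#' These are synthetic stand-in constants representing regular B-DNA
#' geometry; override with survey values if available.
#' @export
bdna_reference_distances <- c(intra = 3.7, inter = 3.0)

#' Compare calibrated distances to regular B-DNA geometry
#'
#' Splits H1'-H6/H8 distance estimates into an outer and a central
#' sequence region and reports the mean deviation from the B-DNA
#' reference, separately for intranucleotide and sequential
#' internucleotide pairs.
#'
#' @param distances list of \code{distance_estimate} whose pairs are
#'   H1'-H6/H8 contacts.
#' @param region_split positions with |position| >= region_split count as
#'   outer (default 4).
#' @param reference named vector c(intra =, inter =) of reference
#'   distances, Angstrom.
#' @return data frame (region, type, n, mean_d, mean_deviation, sign);
#'   pairs that are not H1'-H6/H8 are excluded with a warning.
#' @export
compare_to_bdna <- function(distances, region_split = 4,
                            reference = bdna_reference_distances) {
  if (inherits(distances, "distance_estimate")) distances <- list(distances)
  rows <- lapply(distances, function(de) {
    a <- tryCatch(.parse_atom(de$pair[1]), error = function(e) NULL)
    b <- tryCatch(.parse_atom(de$pair[2]), error = function(e) NULL)
    if (is.null(a) || is.null(b)) return(NULL)
    atoms <- c(a$atom, b$atom)
    if (!("H1'" %in% atoms) || !any(atoms %in% c("H6", "H8"))) return(NULL)
    type <- if (a$position == b$position) "intra" else "inter"
    pos <- max(abs(a$position), abs(b$position))
    data.frame(region = if (pos >= region_split) "outer" else "central",
               type = type, d = de$d)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped)
    warning(dropped, " pair(s) not of H1'-H6/H8 type excluded")
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    return(data.frame(region = character(0), type = character(0),
                      n = integer(0), mean_d = numeric(0),
                      mean_deviation = numeric(0), sign = character(0)))
  agg <- do.call(rbind, lapply(split(tab, list(tab$region, tab$type),
                                     drop = TRUE), function(g) {
    dev <- mean(g$d) - reference[[g$type[1]]]
    data.frame(region = g$region[1], type = g$type[1], n = nrow(g),
               mean_d = mean(g$d), mean_deviation = dev,
               sign = if (abs(dev) < 1e-12) "unchanged"
                      else if (dev < 0) "shortened" else "lengthened")
  }))
  rownames(agg) <- NULL
  agg
}

#' Export a distance-restraint table for restrained MD
#'
#' Bounds are lower = d (1 - f) - a and upper = d (1 + f) + a with a
#' fractional half-width f and absolute padding a (Angstrom).  The table
#' is written as TSV (atom_a, atom_b, target, lower, upper) suitable for
#' conversion to any MD engine's flat-well restraint format.
#'
#' @param distances list of \code{distance_estimate}.
#' @param path output TSV path; NULL to return the data frame only.
#' @param f fractional bound half-width (default 0.2).
#' @param a absolute bound padding, Angstrom (default 0).
#' @return the restraint data frame, invisibly when written to file.
#' @export
export_restraints <- function(distances, path = NULL, f = 0.2, a = 0) {
  if (inherits(distances, "distance_estimate")) distances <- list(distances)
  tab <- if (length(distances))
    do.call(rbind, lapply(distances, function(de)
      data.frame(atom_a = de$pair[1], atom_b = de$pair[2],
                 target = de$d,
                 lower = de$d * (1 - f) - a,
                 upper = de$d * (1 + f) + a)))
  else
    data.frame(atom_a = character(0), atom_b = character(0),
               target = numeric(0), lower = numeric(0), upper = numeric(0))
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Read a restraint table written by \code{\link{export_restraints}}
#' @param path TSV path.
#' @return data frame (atom_a, atom_b, target, lower, upper).
#' @export
read_restraints <- function(path) {
  # quote = "": atom names contain primes (H1')
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' Read a Sparky-style peak list
#'
#' Whitespace-delimited columns: assignment, w1 (ppm), w2 (ppm), volume;
#' lines starting with \code{#} are comments.  Assignments follow the
#' Sparky convention \code{RES1ATOM1-RES2ATOM2}, e.g.
#' \code{C-4H5-C-4H6}.  Peaks with non-positive volume are retained but
#' flagged unusable in \code{assignment_note}.
#'
#' @param path peak-list path.
#' @return list of \code{cross_peak}.
#' @export
read_peaklist <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  peaks <- list()
  for (i in which(keep)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop("malformed peak-list line ", i, ": ", lines[i])
    m <- regmatches(tok[1],
                    regexec("^([ACGT]-?[0-9]+)([A-Z][A-Z0-9']*?)-([ACGT]-?[0-9]+)([A-Z][A-Z0-9']*)$",
                            tok[1]))[[1]]
    if (length(m) != 5)
      stop("malformed assignment on line ", i, ": ", tok[1])
    vol <- suppressWarnings(as.numeric(tok[4]))
    if (is.na(vol))
      stop("non-numeric volume on line ", i, ": ", tok[4])
    note <- if (vol <= 0) "unusable: non-positive volume" else ""
    peaks[[length(peaks) + 1L]] <-
      cross_peak(paste(m[2], m[3]), paste(m[4], m[5]), vol, note)
  }
  peaks
}
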