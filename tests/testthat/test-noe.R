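test_that("reference calibration averages the cytosine H5-H6 volumes", {
  pks <- list(cross_peak("C-4 H5", "C-4 H6", 1),
              cross_peak("C-5 H6", "C-5 H5", 2),   # order-insensitive
              cross_peak("C-7 H5", "C-7 H6", 3),
              cross_peak("A6 H8", "A6 H1'", 50))
  I_ref <- calibrate_reference(pks)
  expect_equal(as.numeric(I_ref), 2)
  expect_equal(attr(I_ref, "n_ref"), 3L)
  expect_equal(as.numeric(calibrate_reference(
    list(cross_peak("C-4 H5", "C-4 H6", 7)))), 7)
  expect_error(calibrate_reference(
    list(cross_peak("A6 H8", "A6 H1'", 1))), "no CH5-H6")
})

test_that("the sixth-power rule converts volumes to distances", {
  I_ref <- 1000
  expect_equal(peak_to_distance(cross_peak("A6 H8", "A6 H1'", 1000),
                                I_ref)$d, 2.9)
  # 64-fold weaker peak doubles the distance; 64-fold stronger halves it
  expect_equal(peak_to_distance(cross_peak("A", "B", 1000 / 64), I_ref)$d,
               5.8, tolerance = 1e-12)
  expect_equal(peak_to_distance(cross_peak("A", "B", 64000), I_ref)$d,
               1.45, tolerance = 1e-12)
  expect_error(peak_to_distance(cross_peak("A", "B", -1), I_ref),
               "non-positive")
})

test_that("distances are scale-invariant and monotone in volume", {
  geom <- tiny_geometry()
  for (k in c(1, 17.3)) {
    pks <- synth_noesy_peaks(geom, scale = 1e6 * k,
                             cfg = synth_config(seed = 1, noise_sigma = 0))
    d <- vapply(peaks_to_distances(pks), `[[`, numeric(1), "d")
    expect_equal(unname(d), geom$d, tolerance = 1e-10)  # closure, any scale
  }
  vols <- c(100, 400, 1000)
  ds <- vapply(vols, function(v)
    peak_to_distance(cross_peak("A", "B", v), 1000)$d, numeric(1))
  expect_true(all(diff(ds) < 0))
})

test_that("small volume noise is compressed by the sixth root", {
  geom <- tiny_geometry()
  pks <- synth_noesy_peaks(geom, cfg = synth_config(seed = 2,
                                                    noise_sigma = 0.05))
  d <- unname(vapply(peaks_to_distances(pks), `[[`, numeric(1), "d"))
  # calibration offsets cancel against the shared reference; individual
  # 5% volume errors propagate as ~1% distance errors
  expect_lt(max(abs(d - geom$d) / geom$d), 0.02)
})

test_that("symmetric cross-peaks are volume-averaged before conversion", {
  pks <- list(cross_peak("C-4 H5", "C-4 H6", 900),
              cross_peak("C-4 H6", "C-4 H5", 1100),
              cross_peak("A6 H8", "A6 H1'", 500))
  d <- peaks_to_distances(pks)
  expect_equal(length(d), 2L)
  expect_equal(d[[1]]$I, 1000)
})

test_that("B-DNA comparison splits regions and signs deviations", {
  ref <- bdna_reference_distances
  mk <- function(res_a, atom_a, res_b, atom_b, d)
    structure(list(pair = c(paste(res_a, atom_a), paste(res_b, atom_b)),
                   d = d, I = 1, I_ref = 1, d_ref = 2.9),
              class = "distance_estimate")
  dist <- list(
    mk("A8", "H1'", "A8", "H8", ref["intra"]),        # outer intra, exact
    mk("T-8", "H1'", "G7", "H8", ref["inter"]),       # outer inter, exact
    mk("A-1", "H1'", "A-1", "H8", ref["intra"] - 0.3),# central intra short
    mk("T1", "H1'", "T2", "H6", ref["inter"] + 0.2))  # central inter long
  rep <- compare_to_bdna(dist)
  outer_rows <- rep[rep$region == "outer", ]
  expect_true(all(abs(outer_rows$mean_deviation) < 1e-12))
  central_intra <- rep[rep$region == "central" & rep$type == "intra", ]
  expect_equal(central_intra$sign, "shortened")
  expect_equal(central_intra$mean_deviation, -0.3, tolerance = 1e-12,
               ignore_attr = TRUE)
  central_inter <- rep[rep$region == "central" & rep$type == "inter", ]
  expect_equal(central_inter$sign, "lengthened")
  # pairs of other types are excluded with a warning
  expect_warning(compare_to_bdna(c(dist, list(mk("A6", "H2", "A-3", "H2",
                                                 3.5)))),
                 "excluded")
})

test_that("restraint export applies the bound rule and round-trips", {
  d29 <- peak_to_distance(cross_peak("C-4 H5", "C-4 H6", 10), 10)
  tab <- export_restraints(list(d29))
  expect_equal(tab$lower, 2.32)
  expect_equal(tab$upper, 3.48)

  f <- tempfile(fileext = ".tsv")
  geom <- tiny_geometry()
  dists <- peaks_to_distances(synth_noesy_peaks(
    geom, cfg = synth_config(seed = 1, noise_sigma = 0)))
  export_restraints(dists, f)
  back <- read_restraints(f)
  expect_equal(back$target, unname(vapply(dists, `[[`, numeric(1), "d")),
               tolerance = 1e-6)
  # empty list still writes a header-only table
  f2 <- tempfile(fileext = ".tsv")
  export_restraints(list(), f2)
  expect_equal(nrow(read_restraints(f2)), 0L)
})

test_that("Sparky-style peak lists parse with comments and flags", {
  f <- tempfile()
  writeLines(c("# assignment w1 w2 volume",
               "",
               "C-4H5-C-4H6 5.62 7.48 1.25e4",
               "A3H1'-A3H8 6.10 8.21 2500",
               "T-2M7-A-1H2 1.44 7.71 -12"), f)
  pks <- read_peaklist(f)
  expect_equal(length(pks), 3L)
  expect_equal(pks[[1]]$atom_a, "C-4 H5")
  expect_equal(pks[[1]]$atom_b, "C-4 H6")
  expect_equal(pks[[2]]$atom_b, "A3 H8")
  expect_equal(pks[[3]]$atom_a, "T-2 M7")
  expect_match(pks[[3]]$assignment_note, "unusable")

  f2 <- tempfile()
  writeLines("# only a comment", f2)
  expect_equal(length(read_peaklist(f2)), 0L)

  f3 <- tempfile()
  writeLines("whatisthis 1 2 3", f3)
  expect_error(read_peaklist(f3), "malformed assignment")
})

test_that("methyl peaks use the three-proton pseudo-atom convention", {
  # generator triples methyl volumes; analysis divides by three: closure
  geom <- data.frame(atom_a = c("C-4 H5", "T2 M7"),
                     atom_b = c("C-4 H6", "A3 H2"),
                     d = c(2.9, 3.8), stringsAsFactors = FALSE)
  pks <- synth_noesy_peaks(geom, cfg = synth_config(seed = 1,
                                                    noise_sigma = 0))
  expect_equal(pks[[2]]$volume / (1e6 * 3.8^-6), 3, tolerance = 1e-12)
  d <- unname(vapply(peaks_to_distances(pks), `[[`, numeric(1), "d"))
  expect_equal(d, geom$d, tolerance = 1e-10)
})
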