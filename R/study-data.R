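# Published summary tables of the brachytherapy SNP follow-up study
# (9 eyes of 9 melanoma patients, Ru-106 plaques). The raw images are not
# deposited; these group-level values are the inputs for the longitudinal
# and dosimetry analyses.

#' Published SNP morphometry group means (normalised to 1 mm^2)
#'
#' Mean and standard deviation of the automated SNP quantification per
#' corneal zone and follow-up visit, for eight of the nine parameters
#' (total fibre length is carried by nerve fibre density). Values are
#' normalised to an area of 1 mm^2 except the average single-fibre length,
#' which is absolute (um).
#'
#' @return long data.frame: metric, zone, timepoint, value (mean), sd.
#' @export
snpStudyMorphometry <- function() {
  metrics <- c("component_pixels", "nerve_fibre_components",
               "skeleton_pixels", "single_nerve_fibres",
               "average_single_fibre_length_um",
               "nerve_fibre_density_mm_per_mm2", "connectivity_points",
               "branches")
  # per metric: applicator / central / distal rows, baseline..month7
  mean_ <- list(
    component_pixels = rbind(
      c(45050.0, 2031.3, 11714.1, 14118.8, 38592.5),
      c(42589.6, 1552.1, 15663.8, 14048.4, 30116.7),
      c(41421.3, 11056.3, 21918.8, 30116.7, 37814.6)),
    nerve_fibre_components = rbind(
      c(50.0, 4.2, 23.4, 31.3, 53.8),
      c(52.1, 2.1, 15.0, 12.5, 66.7),
      c(50.0, 25.0, 14.1, 22.9, 70.8)),
    skeleton_pixels = rbind(
      c(13715.6, 622.9, 3456.3, 4300.0, 11622.5),
      c(12876.0, 460.4, 4627.5, 4217.2, 9110.4),
      c(12722.5, 3347.9, 6585.9, 9077.1, 11422.9)),
    single_nerve_fibres = rbind(
      c(240.6, 4.2, 37.5, 40.6, 188.8),
      c(235.4, 6.3, 51.3, 96.9, 116.7),
      c(162.5, 47.9, 126.6, 175.0, 189.6)),
    average_single_fibre_length_um = rbind(
      c(83.4, 166.4, 101.1, 147.3, 74.2),
      c(74.4, 84.3, 151.9, 83.8, 89.2),
      c(100.2, 93.5, 61.1, 74.4, 68.8)),
    nerve_fibre_density_mm_per_mm2 = rbind(
      c(15.142, 0.693, 3.896, 4.713, 12.945),
      c(14.207, 0.527, 5.322, 4.736, 10.031),
      c(13.827, 3.725, 7.471, 10.151, 12.643)),
    connectivity_points = rbind(
      c(14.2, 0, 1.3, 5.6, 13),
      c(14.2, 0, 2.0, 1.3, 13.3),
      c(13.0, 1.7, 5.6, 8.3, 12.5)),
    branches = rbind(
      c(104.2, 0, 7.8, 4.7, 73.8),
      c(101.0, 2.1, 18.8, 45.3, 25.0),
      c(61.3, 12.5, 62.5, 87.5, 58.3)))
  sd_ <- list(
    component_pixels = rbind(
      c(23273.0, 2637.8, 12851.5, 7941.5, 25383.8),
      c(16506.1, 2688.3, 15369.3, 7681.3, 18365.5),
      c(6598.9, 6637.8, 21252.3, 24992.7, 18680.4)),
    nerve_fibre_components = rbind(
      c(34.7, 3.6, 16.4, 22.8, 26.0),
      c(25.5, 3.6, 13.0, 5.1, 36.1),
      c(40.3, 22.5, 16.4, 7.2, 18.0)),
    skeleton_pixels = rbind(
      c(7004.1, 809.2, 3774.2, 2411.0, 7566.4),
      c(5053.8, 797.5, 4483.7, 2308.7, 5497.3),
      c(1979.2, 2056.2, 6253.7, 7387.1, 5671.4)),
    single_nerve_fibres = rbind(
      c(184.0, 3.6, 39.9, 25.8, 133.4),
      c(167.5, 10.8, 68.4, 112.9, 85.1),
      c(84.7, 28.2, 127.5, 197.3, 108.7)),
    average_single_fibre_length_um = rbind(
      c(34.3, 154.1, 52.4, 77.4, 13.5),
      c(31.2, 0, 65.7, 46.1, 19.4),
      c(37.8, 60.7, 7.9, 22, 7.2)),
    nerve_fibre_density_mm_per_mm2 = rbind(
      c(7.93, 0.908, 4.315, 2.638, 8.586),
      c(5.553, 0.913, 5.205, 2.538, 6.221),
      c(2.279, 2.302, 7.278, 8.627, 6.348)),
    connectivity_points = rbind(
      c(10.4, 0, 2.5, 6.6, 11.5),
      c(6.5, 0, 3.3, 2.5, 10.4),
      c(9.6, 1.4, 6.6, 8.8, 9.0)),
    branches = rbind(
      c(91.8, 0, 15.6, 6.0, 64.1),
      c(101.6, 3.6, 35.1, 59.2, 33.1),
      c(43.6, 16.5, 61.0, 120.5, 54.6)))
  out <- list()
  for (m in metrics) {
    for (z in seq_along(cornealZones())) {
      out[[length(out) + 1L]] <- data.frame(
        metric = m, zone = cornealZones()[z], timepoint = timePoints(),
        value = mean_[[m]][z, ], sd = sd_[[m]][z, ])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Published corneal sensation group means (Cochet-Bonnet, mm)
#'
#' Pre-irradiation sensation was 58 +/- 4 mm in all zones.
#'
#' @return long data.frame: metric ("sensation_mm"), zone, timepoint,
#'   value (mean), sd.
#' @export
snpStudySensation <- function() {
  v <- rbind(
    c(58, 5, 23, 39, 56),    # applicator
    c(58, 8, 23, 41, 57),    # central
    c(58, 23, 37, 50, 54))   # distal
  s <- rbind(
    c(4, 6, 15, 17, 4),
    c(4, 6, 17, 19, 5),
    c(4, 12, 17, 18, 17))
  out <- list()
  for (z in seq_along(cornealZones()))
    out[[z]] <- data.frame(metric = "sensation_mm",
                           zone = cornealZones()[z],
                           timepoint = timePoints(), value = v[z, ],
                           sd = s[z, ])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Published per-patient dosimetry table
#'
#' Demographics, prescribed tumour-base dose, applicator-zone dose rate,
#' and the printed per-zone calculated corneal surface doses of the nine
#' patients.
#'
#' @return data.frame, one row per patient.
#' @export
snpStudyDoses <- function() {
  data.frame(
    patient = 1:9,
    gender = c("F", "M", "F", "F", "F", "F", "F", "M", "M"),
    age = c(73, 65, 46, 50, 76, 40, 66, 61, 73),
    location = c("conjunctiva", "conjunctiva", "iris", "iris",
                 "ciliary body", "conjunctiva", "ciliary body",
                 "ciliary body", "conjunctiva"),
    tumour_height_mm = c(0.5, 7.0, 2.0, 3.0, 3.6, 1.0, 5.0, 1.2, 2.3),
    dose_rate_gy_per_h = c(4.30, 4.64, 5.00, 5.09, 4.94, 7.79, 9.54,
                           7.17, 4.87),
    prescribed_gy = c(278, 293, 550, 520, 527, 387, 1070, 500, 573),
    printed_adjacent_gy = c(1.22, 1.29, 2.42, 2.29, 2.31, 1.70, 4.70,
                            2.20, 2.52),
    printed_central_gy = c(0.33, 0.35, 0.66, 0.62, 0.63, 0.46, 1.28,
                           0.60, 0.69),
    printed_distal_gy = c(0.04, 0.04, 0.08, 0.08, 0.08, 0.06, 0.16,
                          0.08, 0.09))
}
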