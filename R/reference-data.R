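# Published reference values for the four-site Campanian olive germplasm
# survey that this package's defaults emulate: per-locus SSR allele
# frequencies, per-locus diversity summaries, and per-site trait means/sds.
# They parameterise the synthetic generator and serve as desk-check inputs.

.ref_freqs_raw <- list(
  UDO36 = c(`138` = 0.012, `140` = 0.190, `142` = 0.075, `144` = 0.461,
            `148` = 0.003, `150` = 0.006, `152` = 0.235, `154` = 0.006,
            `160` = 0.006, `162` = 0.003, `164` = 0.003),
  UDO6 = c(`144` = 0.012, `146` = 0.373, `160` = 0.088, `162` = 0.003,
           `164` = 0.003, `166` = 0.006, `168` = 0.158, `170` = 0.055,
           `172` = 0.252, `178` = 0.003, `180` = 0.042, `188` = 0.003,
           `190` = 0.003),
  UDO17 = c(`144` = 0.003, `150` = 0.003, `152` = 0.155, `154` = 0.211,
            `156` = 0.082, `158` = 0.007, `160` = 0.118, `162` = 0.280,
            `168` = 0.125, `170` = 0.016),
  GAPU59 = c(`204` = 0.009, `206` = 0.259, `208` = 0.003, `210` = 0.449,
             `212` = 0.006, `214` = 0.003, `216` = 0.098, `218` = 0.003,
             `220` = 0.164, `224` = 0.006),
  GAPU71B = c(`116` = 0.009, `118` = 0.015, `120` = 0.479, `122` = 0.006,
              `124` = 0.015, `126` = 0.140, `128` = 0.003, `140` = 0.330,
              `144` = 0.003),
  UDO39 = c(`104` = 0.012, `144` = 0.093, `164` = 0.003, `170` = 0.503,
            `174` = 0.012, `176` = 0.166, `178` = 0.024, `180` = 0.160,
            `186` = 0.006, `188` = 0.018, `190` = 0.003)
)

#' Reference SSR allele frequencies
#'
#' Published whole-collection allele frequencies for the six SSR loci
#' (UDO36, UDO6, UDO17, GAPU59, GAPU71B, UDO39) scored in the Campanian
#' olive survey the package emulates; frequencies as printed (3 decimals).
#'
#' @return data.frame with columns `locus`, `allele` (bp), `freq`.
#' @export
ref_allele_freqs <- function() {
  do.call(rbind, lapply(names(.ref_freqs_raw), function(l) {
    f <- .ref_freqs_raw[[l]]
    data.frame(locus = l, allele = as.integer(names(f)), freq = unname(f),
               stringsAsFactors = FALSE)
  }))
}

#' Reference per-locus diversity summaries
#'
#' Published per-locus sample sizes and heterozygosities for the same
#' survey: N (trees amplified), observed (Ho) and expected (He)
#' heterozygosity.
#'
#' @return data.frame with columns `locus`, `N`, `Ho`, `He`.
#' @export
ref_locus_stats <- function() {
  data.frame(
    locus = c("UDO36", "UDO6", "UDO17", "GAPU59", "GAPU71B", "UDO39"),
    N = c(166L, 165L, 152L, 168L, 168L, 166L),
    Ho = c(0.910, 0.861, 0.796, 0.792, 0.946, 0.289),
    He = c(0.690, 0.760, 0.817, 0.694, 0.641, 0.684),
    stringsAsFactors = FALSE
  )
}

.ref_traits_raw <- local({
  vars <- c("olive_weight", "major_axis", "leaf_area",
            "C16:0", "C16:1", "C17:1", "C18:1", "C18:1t",
            "C18:2", "C18:3", "C20:0", "C20:1", "C22:0")
  mean <- rbind(
    CE  = c(1.63, 1.81, 4.71, 12.69, 2.23, 0.00, 72.86, 3.84, 7.47, 0.47, 0.45, 0.00, 0.00),
    CM  = c(1.13, 1.71, 7.14, 16.35, 0.90, 0.33, 70.72, 1.49, 8.06, 0.68, 0.63, 0.00, 0.09),
    OIR = c(2.12, 2.03, 4.72, 12.51, 1.03, 0.04, 76.94, 0.27, 5.06, 1.00, 0.02, 0.59, 0.00),
    OSE = c(1.73, 1.82, 5.09, 10.63, 0.54, 0.01, 80.01, 0.00, 6.29, 0.74, 0.00, 0.61, 0.02)
  )
  sd <- rbind(
    CE  = c(0.37, 0.22, 1.06, 0.71, 0.44, 0.00, 1.79, 0.53, 1.22, 0.12, 0.07, 0.00, 0.00),
    CM  = c(0.26, 0.18, 1.63, 2.93, 0.68, 0.09, 3.36, 0.53, 1.66, 0.22, 0.15, 0.00, 0.03),
    OIR = c(0.45, 0.26, 1.24, 1.97, 0.57, 0.11, 5.14, 1.06, 3.46, 0.38, 0.09, 0.20, 0.01),
    OSE = c(0.23, 0.21, 1.32, 1.20, 0.18, 0.02, 3.12, 0.00, 1.68, 0.20, 0.00, 0.09, 0.05)
  )
  colnames(mean) <- colnames(sd) <- vars
  list(mean = mean, sd = sd, vars = vars)
})

#' Reference per-site trait means and standard deviations
#'
#' Published site-level means (and sds) of the three morphometric traits
#' (olive weight g, major drupe axis cm, leaf area cm^2) and the relative
#' abundance (%) of ten fatty acids, for the four collection sites CE, CM,
#' OIR and OSE. Several acids are structural zeros at some sites (entirely
#' absent from those oils) and act as geographic bio-markers.
#'
#' @return list with matrices `mean` and `sd` (site x variable).
#' @export
ref_site_traits <- function() .ref_traits_raw[c("mean", "sd")]

#' Default fatty-acid saturation classes
#'
#' Chemical classification of the ten assayed acids into mono-unsaturated
#' (MUFA), poly-unsaturated (PUFA) and other (saturated) classes, used by
#' [mufa_pufa_ratio()].
#'
#' @return named character vector (acid -> class).
#' @export
default_fatty_classes <- function() {
  c("C16:0" = "other", "C16:1" = "MUFA", "C17:1" = "MUFA",
    "C18:1" = "MUFA", "C18:1t" = "MUFA", "C18:2" = "PUFA",
    "C18:3" = "PUFA", "C20:0" = "other", "C20:1" = "MUFA",
    "C22:0" = "other")
}
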