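# Reference tables for the synthetic cohort generator. Gene symbols are real
# monocyte subset markers; fold changes, baselines and factor-loading
# patterns are synthetic generator parameters chosen to mimic a two-group
# whole-blood signature (directions follow the published subset-level
# up/down proportions; magnitudes are invented).

#' Default monocyte signature-gene table (synthetic calibration)
#'
#' The 54 subset-labeled signature genes the generator simulates: 4 pan,
#' 9 classical, 20 intermediate and 21 nonclassical markers, each with a
#' group log2 fold change (`log2FC`, FES vs HC), a baseline log2-CPM
#' (`base`) and a unitless latent-factor loading pattern (`pattern`).
#' Directions of effect follow the subset-level proportions reported for
#' whole-blood monocyte signatures (most classical markers down, most
#' nonclassical markers up, intermediate mixed, S100A family strongly down,
#' IFITM family strongly up); the numeric values are synthetic.
#'
#' @return data.frame with columns `gene`, `subset`, `log2FC`, `base`,
#'   `pattern`.
#' @export
signatureGeneTable <- function() {
  tab <- rbind(
    data.frame(subset = "pan",
               gene   = c("CLEC7A", "CSF1R", "ITGAM", "CD86"),
               log2FC = c(0.45, -0.25, -0.22, 0.28)),
    data.frame(subset = "classical",
               gene   = c("RNASE2", "CD14", "CCR2", "SELL", "VCAN", "CD36",
                          "NAIP", "TREM1", "FCN1"),
               log2FC = c(-0.41, -0.30, -0.26, -0.35, -0.24, -0.21,
                          0.38, 0.27, 0.22)),
    data.frame(subset = "intermediate",
               gene   = c("S100A8", "S100A9", "S100A12", "HLA-DRA",
                          "HLA-DRB1", "HLA-DPA1", "HLA-DPB1", "CD74",
                          "CLEC10A", "MRC1", "CD163", "PROK2", "CR1",
                          "ITGA4", "ITGAX", "CSF2RA", "CSF1", "TLR4",
                          "IL6R", "CCR5"),
               log2FC = c(-0.72, -0.65, -0.80, -0.28, -0.31, -0.24, -0.22,
                          -0.26, -0.23, -0.21, -0.33, 0.55, 0.29, 0.24,
                          0.27, 0.22, 0.25, 0.23, 0.21, 0.26)),
    data.frame(subset = "nonclassical",
               gene   = c("IFITM2", "IFITM3", "FCGR3A", "CX3CR1", "CDKN1C",
                          "MS4A7", "RHOC", "TCF7L2", "C1QA", "C1QB", "C1QC",
                          "HES4", "SMIM25", "LYPD2", "SIGLEC10", "CKB",
                          "ICAM4", "VMO1", "PECAM1", "LRRC25", "NR4A1"),
               log2FC = c(0.62, 0.70, 0.35, 0.24, 0.41, 0.28, 0.26, 0.22,
                          0.31, 0.29, 0.27, 0.33, 0.25, -0.27, -0.22,
                          -0.25, -0.21, -0.30, -0.23, -0.26, -0.36))
  )
  tab$subset <- factor(tab$subset,
                       c("pan", "classical", "intermediate", "nonclassical"))
  # deterministic heterogeneous baselines (log2-CPM) and loading patterns
  tab$base <- 4 + 6 * (order(order(tab$gene)) - 1) / (nrow(tab) - 1)
  tab$base[tab$gene == "S100A8"] <- 11
  tab$base[tab$gene == "S100A9"] <- 10.5
  tab$pattern <- seq(0.5, 1.5, length.out = nrow(tab))
  rownames(tab) <- NULL
  tab[, c("gene", "subset", "log2FC", "base", "pattern")]
}

#' Default cortical-region table (synthetic calibration)
#'
#' The 34 bilateral Desikan-Killiany regions with a typical mean thickness
#' (mm, scaled so the whole-cortex mean is 2.59 mm), a group thickness shift
#' (FES minus HC, mm; eight parietal/temporal/occipital regions thinner,
#' pericalcarine and lingual slightly thicker, mean shift about -0.05 mm)
#' and a unitless latent-factor loading pattern.
#'
#' @return data.frame with columns `region`, `mean`, `shift`, `pattern`.
#' @export
corticalRegionTable <- function() {
  region <- dkRegions()
  mean <- c(2.55, 2.65, 2.60, 1.95, 3.30, 2.80, 2.75, 2.50, 2.80, 3.10,
            2.45, 2.20, 2.70, 2.05, 2.50, 2.85, 2.45, 2.80, 2.65, 2.70,
            2.55, 1.65, 2.10, 2.50, 2.60, 2.40, 2.85, 2.45, 2.75, 2.25,
            2.80, 2.55, 3.60, 2.40)
  mean <- mean * 2.59 / base::mean(mean)
  thinner <- c("supramarginal", "inferiorparietal", "superiorparietal",
               "lateraloccipital", "inferiortemporal", "precuneus",
               "fusiform", "superiortemporal")
  thicker <- c("pericalcarine", "lingual")
  shift <- rep(-0.043, length(region))
  shift[region %in% thinner] <- -0.09
  shift[region %in% thicker] <- 0.04
  data.frame(region = region, mean = mean, shift = shift,
             pattern = seq(0.5, 1.5, length.out = length(region)))
}

#' Default MCCB domain table (synthetic calibration)
#'
#' The seven MCCB cognitive domains plus the composite, with control-group
#' mean and SD, patient-group SD, the group shift (FES minus HC, T-score
#' units) and a unitless latent-factor loading pattern. Means, SDs and
#' shifts follow the magnitudes typical of first-episode psychosis cohorts
#' (composite deficit about -13.8 T).
#'
#' @return data.frame with columns `domain`, `mean_hc`, `sd_hc`, `sd_fes`,
#'   `shift`, `pattern`.
#' @export
mccbDomainTable <- function() {
  data.frame(
    domain = c(mccbDomains(), "mccb_composite"),
    mean_hc = c(57.50, 57.17, 57.55, 57.37, 55.02, 56.63, 54.46, 58.69),
    sd_hc   = c(8.73, 10.83, 7.17, 7.78, 7.22, 7.40, 10.08, 6.98),
    sd_fes  = c(11.05, 11.91, 10.94, 10.98, 9.78, 10.33, 11.16, 9.30),
    shift   = c(-13.18, -16.67, -11.55, -8.65, -9.49, -9.65, -8.14, -13.76),
    pattern = c(seq(0.7, 1.3, length.out = 7), 1.0)
  )
}
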