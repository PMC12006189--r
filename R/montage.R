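#' Canonical 19-channel 10-20 montage
#'
#' The package works on the classical 19-electrode subset of the
#' international 10-20 system. Two naming conventions for the four
#' temporo-parietal electrodes circulate in clinical practice: modern
#' amplifiers label them T7/P7/P8/T8 while the older convention uses
#' T3/T5/T6/T4 for the same scalp positions. All functions in this package
#' operate on the older labels, in the fixed order returned here.
#'
#' @return Character vector of 19 channel labels in canonical order.
#' @export
#' @examples
#' canonical_montage()
canonical_montage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz",
    "T3", "T4", "C3", "C4", "Cz",
    "P3", "P4", "Pz", "T5", "T6", "O1", "O2")
}

# modern-name synonyms for the four electrodes whose labels differ
.montage_synonyms <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Schematic 2-D scalp coordinates for the canonical montage
#'
#' Approximate top-view positions (nose up, unit head radius) of the 19
#' electrodes, used when exporting `.node` files for brain-network viewers.
#'
#' @return Data frame with columns `label`, `x`, `y`.
#' @export
electrode_positions <- function() {
  pos <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    F7  = c(-0.81, 0.59), F3  = c(-0.43, 0.55), Fz = c(0, 0.50),
    F4  = c(0.43, 0.55),  F8  = c(0.81, 0.59),
    T3  = c(-1.00, 0.00), C3  = c(-0.50, 0.00), Cz = c(0, 0.00),
    C4  = c(0.50, 0.00),  T4  = c(1.00, 0.00),
    T5  = c(-0.81, -0.59), P3 = c(-0.43, -0.55), Pz = c(0, -0.50),
    P4  = c(0.43, -0.55), T6  = c(0.81, -0.59),
    O1  = c(-0.31, -0.95), O2 = c(0.31, -0.95)
  )
  labs <- canonical_montage()
  data.frame(label = labs, x = pos[labs, 1], y = pos[labs, 2],
             row.names = NULL)
}
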