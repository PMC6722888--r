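#' Construct a channel panel
#'
#' A panel is an ordered table of isotope channels: the metal tag, the
#' marker (antibody or intercalator) it carries, and the subcellular
#' compartment the marker localizes to. Panel order defines the page order
#' of every TIFF stack and the channel order of every image array.
#'
#' @param metal_tag Character vector of isotope tags (e.g. `"Ir191"`).
#' @param marker Character vector of marker names; must be unique.
#' @param compartment One of `"nucleus"`, `"cytoplasm"`, `"membrane"`,
#'   `"any"` per channel.
#' @return A tibble of class `imc_panel` with columns
#'   `metal_tag`, `marker`, `compartment`.
#' @export
imc_panel <- function(metal_tag, marker, compartment) {
  abort_if(length(metal_tag) != length(marker) ||
             length(marker) != length(compartment),
           "metal_tag, marker and compartment must have equal length")
  abort_if(anyDuplicated(marker) > 0, "duplicated marker names in panel")
  bad <- setdiff(unique(compartment),
                 c("nucleus", "cytoplasm", "membrane", "any"))
  abort_if(length(bad) > 0, "unknown compartment class: %s",
           paste(bad, collapse = ", "))
  out <- tibble::tibble(metal_tag = as.character(metal_tag),
                        marker = as.character(marker),
                        compartment = as.character(compartment))
  class(out) <- c("imc_panel", class(out))
  out
}

#' The default 29-channel MCF-7 drug-profiling panel
#'
#' Nuclear identification channels (the two iridium intercalator isotopes),
#' a viability channel, an S-phase label, nuclear state markers (mitosis,
#' DNA damage, proliferation, cell-cycle and signaling proteins), epithelial
#' cytoskeleton markers, surface adhesion/CD markers, and a carrier blank.
#'
#' @return An [imc_panel()] with exactly 29 channels.
#' @export
default_panel <- function() {
  imc_panel(
    metal_tag = c("Ir191", "Ir193", "Rh103", "I127", "Eu153", "Gd155",
                  "Er168", "Sm152", "Dy164", "Er166", "Yb172", "Yb174",
                  "Nd146", "Nd148", "Nd142", "Tb159", "Nd150", "Nd143",
                  "Yb171", "Nd144", "Sm149", "Gd156", "Eu151", "Gd160",
                  "Nd145", "Dy162", "Sm147", "Pr141", "Pt195"),
    marker = c("Ir191-DNA", "Ir193-DNA", "Rh103-viability", "IdU",
               "pHistone3-S28", "pH2A.X-S139", "Ki-67", "p53", "cyclinB1",
               "cyclinD3", "p4E-BP1", "cPARP", "ERalpha", "pan-keratin",
               "CK19", "MUC-1", "EpCAM", "CD29", "CD81", "CD98", "CD47",
               "CD49e", "E-cadherin", "EGFR", "HER2", "CD107b", "vimentin",
               "CK5", "carrier-blank"),
    compartment = c("nucleus", "nucleus", "any", "nucleus", "nucleus",
                    "nucleus", "nucleus", "nucleus", "nucleus", "nucleus",
                    "nucleus", "nucleus", "nucleus", "cytoplasm",
                    "cytoplasm", "membrane", "membrane", "membrane",
                    "membrane", "membrane", "membrane", "membrane",
                    "membrane", "membrane", "membrane", "cytoplasm",
                    "cytoplasm", "cytoplasm", "any")
  )
}

#' Read / write a panel CSV
#'
#' The on-disk format is a UTF-8 CSV with columns
#' `metal_tag,marker,compartment`, in channel (stack page) order.
#'
#' @param path File path.
#' @return `read_panel()` returns an [imc_panel()]; `write_panel()`
#'   returns `path` invisibly.
#' @export
read_panel <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  abort_if(!all(c("metal_tag", "marker", "compartment") %in% names(df)),
           "panel CSV must have columns metal_tag, marker, compartment")
  imc_panel(df$metal_tag, df$marker, df$compartment)
}

#' @rdname read_panel
#' @param panel An [imc_panel()].
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(tibble::as_tibble(panel)[, c("metal_tag", "marker",
                                                "compartment")], path,
                   progress = FALSE)
  invisible(path)
}
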