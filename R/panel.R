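#' Detector layout of the packaged 3-laser instrument configuration
#'
#' 38 detectors: 16 on the violet (405 nm), 14 on the blue (488 nm) and 8 on
#' the red (640 nm) laser, each characterized by its center wavelength.
#'
#' @return Data frame with `detector`, `laser`, `wavelength` (nm).
#' @export
instrument_detectors <- function() {
  wl <- c(seq(420, 820, length.out = 16),
          seq(500, 820, length.out = 14),
          seq(650, 820, length.out = 8))
  laser <- rep(c("violet", "blue", "red"), c(16, 14, 8))
  idx <- c(seq_len(16), seq_len(14), seq_len(8))
  data.frame(detector = paste0(toupper(substr(laser, 1, 1)), idx),
             laser = laser, wavelength = wl)
}

# deterministic per-dye cross-excitation so same-peak dyes on different
# lasers (PE-Cy7 vs APC-Cy7) stay linearly independent
.cross_excitation <- function(fluorophore, primary) {
  h <- sum(utf8ToInt(fluorophore)) %% 97
  base <- c(violet = 0.05, blue = 0.08, red = 0.03)
  w <- base + 0.10 * ((h * c(7, 13, 29)) %% 23) / 23
  names(w) <- c("violet", "blue", "red")
  w[primary] <- 1
  w
}

#' Synthesize a fluorophore emission fingerprint
#'
#' Builds a plausible spectral signature for a dye from its approximate
#' emission peak and primary excitation laser: within each laser block the
#' emission is a Gaussian bump centered at `peak_nm`, scaled by that laser's
#' excitation efficiency (1 for the primary laser, a small deterministic
#' dye-specific weight for the others). Synthetic by construction; it is not
#' a measured spectrum.
#'
#' @param fluorophore Dye name.
#' @param peak_nm Approximate emission peak (nm).
#' @param laser Primary excitation laser: `"violet"`, `"blue"` or `"red"`.
#' @param width Gaussian emission width (nm).
#' @param detectors Detector layout, defaults to [instrument_detectors()].
#' @return A `spectral_signature`.
#' @export
synthetic_signature <- function(fluorophore, peak_nm, laser,
                                width = 35, detectors = instrument_detectors()) {
  laser <- match.arg(laser, c("violet", "blue", "red"))
  ex <- .cross_excitation(fluorophore, laser)
  v <- ex[detectors$laser] * exp(-0.5 * ((detectors$wavelength - peak_nm) / width)^2)
  s <- spectral_signature(fluorophore, v)
  names(s$intensities) <- detectors$detector
  s
}

panel_signature_list <- function(x) {
  if (inherits(x, "panel_definition")) return(x$signatures)
  if (inherits(x, "spectral_signature")) return(list(x))
  if (is.list(x)) {
    return(lapply(seq_along(x), function(i) {
      s <- x[[i]]
      if (inherits(s, "spectral_signature")) s
      else spectral_signature(names(x)[i] %||% paste0("S", i), sig_vec(s))
    }))
  }
  cs_abort("expected a panel_definition or list of signatures", "input")
}

.panel_categories <- c("lineage", "activation", "inhibitory",
                       "maturation", "viability")

#' Build a panel definition
#'
#' A panel is the ordered marker/fluorophore assignment of one staining
#' tube, together with each fluorophore's spectral signature, the marker
#' category used for heatmap color coding, and the titrated antibody
#' concentration.
#'
#' @param channels Data frame with columns `marker`, `fluorophore`,
#'   `category` (one of lineage, activation, inhibitory, maturation,
#'   viability), `concentration` (uL/test), `peak_nm`, `laser`.
#' @param name Panel name.
#' @return A `panel_definition`: list with `name`, `channels`, `signatures`
#'   (list of `spectral_signature`, one per channel) and `detectors`.
#' @export
panel_definition <- function(channels, name = "panel") {
  need <- c("marker", "fluorophore", "category", "concentration",
            "peak_nm", "laser")
  if (!is.data.frame(channels) || !all(need %in% names(channels))) {
    cs_abort(paste("panel `channels` must be a data frame with columns:",
                   paste(need, collapse = ", ")), "schema")
  }
  if (anyDuplicated(channels$fluorophore)) {
    cs_abort("duplicate fluorophore in panel", "schema")
  }
  if (anyDuplicated(channels$marker)) {
    cs_abort("duplicate marker in panel", "schema")
  }
  bad <- setdiff(channels$category, .panel_categories)
  if (length(bad)) {
    cs_abort(paste("unknown channel category:", paste(bad, collapse = ", ")),
             "schema")
  }
  det <- instrument_detectors()
  sigs <- Map(synthetic_signature, channels$fluorophore, channels$peak_nm,
              channels$laser, MoreArgs = list(detectors = det))
  names(sigs) <- channels$fluorophore
  structure(list(name = name,
                 channels = as.data.frame(channels),
                 signatures = unname(sigs),
                 detectors = det),
            class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("<panel_definition>", x$name, "-", nrow(x$channels), "channels,",
      nrow(x$detectors), "detectors\n")
  print(utils::head(x$channels[, c("marker", "fluorophore", "category",
                                   "concentration")], 8))
  if (nrow(x$channels) > 8) cat("...\n")
  invisible(x)
}

#' Load a panel definition from YAML or JSON
#'
#' The file must contain a `channels` list whose entries carry `marker`,
#' `fluorophore`, `category`, `concentration`, `peak_nm` and `laser`
#' fields. The two packaged fixtures (`pbmc_panel()`, `tcell_panel()`)
#' mirror the published 22-color PBMC and T-cell panels.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `panel_definition`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) cs_abort(paste("no such panel file:", path), "io")
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(spec$channels)) {
    cs_abort("panel file is missing the `channels` key", "schema")
  }
  rows <- lapply(spec$channels, function(ch) {
    miss <- setdiff(c("marker", "fluorophore", "category", "concentration",
                      "peak_nm", "laser"), names(ch))
    if (length(miss)) {
      cs_abort(paste("panel channel missing fields:",
                     paste(miss, collapse = ", ")), "schema")
    }
    data.frame(marker = ch$marker, fluorophore = ch$fluorophore,
               category = ch$category,
               concentration = as.numeric(ch$concentration),
               peak_nm = as.numeric(ch$peak_nm), laser = ch$laser)
  })
  panel_definition(do.call(rbind, rows), name = spec$name %||% basename(path))
}

#' Write a panel definition to YAML or JSON
#' @param panel A `panel_definition`.
#' @param path Output path, extension selects the format.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_definition"))
  spec <- list(name = panel$name,
               channels = lapply(seq_len(nrow(panel$channels)), function(i) {
                 as.list(panel$channels[i, c("marker", "fluorophore",
                                             "category", "concentration",
                                             "peak_nm", "laser")])
               }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(spec, path)
  }
  invisible(path)
}

#' Packaged 22-color PBMC immunophenotyping panel
#' @return A `panel_definition` with 22 channels (incl. viability dye).
#' @export
pbmc_panel <- function() {
  load_panel(system.file("extdata", "pbmc_panel.yaml",
                         package = "cytoscreen", mustWork = TRUE))
}

#' Packaged 22-color T-cell immunophenotyping panel
#' @return A `panel_definition` with 22 channels (incl. viability dye).
#' @export
tcell_panel <- function() {
  load_panel(system.file("extdata", "tcell_panel.yaml",
                         package = "cytoscreen", mustWork = TRUE))
}
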