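#' VOC channel registry
#'
#' A channel registry maps exact PTR-TOF-MS ion masses (m/z of the protonated
#' ion) to ion formulae, compound labels and one of six biosynthetic VOC
#' groups used throughout the package: `isoprene` (MEP pathway), `lox`
#' (lipoxygenase-pathway green leaf volatiles), `carbonyls` (reactive
#' oxidative carbonyls), `methanol` (cell-wall pectin demethylation), `acids`
#' (short-chain organic acids) and `ethanol` (fermentation marker).
#'
#' `default_channel_registry()` returns the registry of the 16 channels the
#' package monitors by default.  Note the near-isobaric pairs 47.013
#' (formic acid) / 47.049 (ethanol) and 59.014 (glyoxal) / 59.049
#' (propanal/acetone), which any matching tolerance must resolve.
#'
#' The acetaldehyde row records the conventional channel at m/z 45.034; the
#' `note` column flags that the commonly quoted ion formula for this channel
#' is inconsistent with protonated acetaldehyde (C2H5O+), so the registry
#' keys on the m/z value rather than the formula.
#'
#' @return A tibble with columns `mz` (Da), `ion_formula`, `compound`,
#'   `group` and `note`.
#' @examples
#' default_channel_registry()
#' @export
default_channel_registry <- function() {
  tibble::tribble(
    ~mz,     ~ion_formula, ~compound,            ~group,
    69.070,  "C5H9+",      "isoprene",           "isoprene",
    99.080,  "C6H11O+",    "hexenals",           "lox",
    101.096, "C6H13O+",    "hexanal_hexenols",   "lox",
    143.107, "C8H15O2+",   "hexenyl_acetate",    "lox",
    87.080,  "C5H11O+",    "pentanal_pentenol",  "lox",
    45.034,  "C2H2O+",     "acetaldehyde",       "carbonyls",
    59.049,  "C3H7O+",     "propanal_acetone",   "carbonyls",
    73.065,  "C4H9O+",     "butanal_mek",        "carbonyls",
    71.049,  "C4H7O+",     "mvk_macr",           "carbonyls",
    75.045,  "C3H7O2+",    "hydroxyacetone",     "carbonyls",
    59.014,  "C2H3O2+",    "glyoxal",            "carbonyls",
    73.028,  "C3H5O2+",    "methylglyoxal",      "carbonyls",
    33.034,  "CH5O+",      "methanol",           "methanol",
    47.013,  "CH3O2+",     "formic_acid",        "acids",
    61.028,  "C2H5O2+",    "acetic_acid",        "acids",
    47.049,  "C2H7O+",     "ethanol",            "ethanol"
  ) |>
    dplyr::mutate(note = dplyr::if_else(
      .data$mz == 45.034,
      "printed ion formula inconsistent with protonated acetaldehyde; keyed on m/z",
      NA_character_
    ))
}

#' Names of the six biosynthetic VOC groups
#' @return Character vector of the six group labels.
#' @export
voc_groups <- function() {
  c("isoprene", "lox", "carbonyls", "methanol", "acids", "ethanol")
}

validate_registry <- function(registry, tolerance = 0.01) {
  req <- c("mz", "compound", "group")
  miss <- setdiff(req, names(registry))
  if (length(miss) > 0) {
    abort(paste0("registry is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(registry$mz)) || any(registry$mz <= 0)) {
    abort("registry m/z values must be positive and finite")
  }
  bad <- setdiff(unique(registry$group), voc_groups())
  if (length(bad) > 0) {
    abort(paste0("unknown VOC group(s) in registry: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(registry$compound)) {
    abort("registry compound labels must be unique")
  }
  # all channel pairs must be separable at the working tolerance
  d <- abs(outer(registry$mz, registry$mz, "-"))
  diag(d) <- Inf
  if (any(d < 2 * tolerance - 1e-12)) {
    i <- which(d < 2 * tolerance - 1e-12, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "registry channels %.3f and %.3f are not distinguishable at tolerance +/-%.3f Da",
      registry$mz[i[1]], registry$mz[i[2]], tolerance
    ))
  }
  invisible(registry)
}

#' Assign observed ion masses to registry channels
#'
#' Each observed m/z is assigned to the nearest registry channel within
#' `tolerance`; masses with no channel within tolerance are returned as
#' unassigned.  If two registry channels both lie within tolerance of one
#' observed mass the assignment is ambiguous and the call fails, naming both
#' candidates, rather than guessing.
#'
#' @param observed_mz Numeric vector of observed ion masses (Da).
#' @param registry Channel registry tibble; see [default_channel_registry()].
#' @param tolerance Match tolerance in Da (default +/-0.01, tight enough to
#'   resolve the 47.013/47.049 and 59.014/59.049 near-isobars).
#' @return A tibble with one row per observed mass: `observed_mz`, `mz`
#'   (matched channel or `NA`), `compound`, `group`, `delta_mz`, `assigned`.
#' @examples
#' map_channels(c(69.071, 47.05, 999), default_channel_registry())
#' @export
map_channels <- function(observed_mz, registry = default_channel_registry(),
                         tolerance = 0.01) {
  if (!is.numeric(tolerance) || tolerance <= 0) abort("tolerance must be > 0")
  validate_registry(registry)
  rows <- purrr::map(observed_mz, function(m) {
    d <- abs(registry$mz - m)
    hits <- which(d <= tolerance)
    if (length(hits) > 1) {
      abort(sprintf(
        "observed m/z %.4f is ambiguous at +/-%.3f Da: matches %s (%.3f) and %s (%.3f)",
        m, tolerance,
        registry$compound[hits[1]], registry$mz[hits[1]],
        registry$compound[hits[2]], registry$mz[hits[2]]
      ))
    }
    if (length(hits) == 1) {
      tibble::tibble(
        observed_mz = m, mz = registry$mz[hits],
        compound = registry$compound[hits], group = registry$group[hits],
        delta_mz = m - registry$mz[hits], assigned = TRUE
      )
    } else {
      tibble::tibble(
        observed_mz = m, mz = NA_real_, compound = NA_character_,
        group = NA_character_, delta_mz = NA_real_, assigned = FALSE
      )
    }
  })
  dplyr::bind_rows(rows)
}

#' Read or write a channel registry CSV
#'
#' The interchange format is a CSV with columns
#' `mz, ion_formula, compound, group` plus optional `k_rate` (proton-transfer
#' reaction rate constant, used only by the optional counts-to-mixing-ratio
#' helper) and `note`.
#'
#' @param path File path.
#' @param registry Registry tibble to write.
#' @return `read_registry()` returns a validated registry tibble;
#'   `write_registry()` returns `path` invisibly.
#' @export
read_registry <- function(path) {
  reg <- readr::read_csv(path, show_col_types = FALSE)
  validate_registry(reg)
  reg
}

#' @rdname read_registry
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  readr::write_csv(registry, path)
  invisible(path)
}

#' Mixing ratio from raw ion count rates (optional helper)
#'
#' Standard proton-transfer kinetic conversion
#' \eqn{\chi = I_{prod} / (I_{prim} \, k \, t)} from product and primary ion
#' count rates, the channel's reaction rate constant and the drift-tube
#' reaction time.  The package's default path consumes channel-level mixing
#' ratios directly; this helper exists for workflows that start from counts.
#'
#' @param count_product Product ion count rate (counts per second).
#' @param count_primary Primary (H3O+) ion count rate (counts per second).
#' @param k_rate Reaction rate constant (cm3 s-1), per channel.
#' @param t_react Reaction time in the drift tube (s).
#' @param number_density Drift-tube gas number density (cm-3).
#' @return Mixing ratio in nmol mol-1.
#' @export
mixing_ratio_from_counts <- function(count_product, count_primary, k_rate,
                                     t_react, number_density) {
  stopifnot(count_primary > 0, k_rate > 0, t_react > 0, number_density > 0)
  # volume mixing ratio, converted to nmol/mol
  (count_product / (count_primary * k_rate * t_react * number_density)) * 1e9
}
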