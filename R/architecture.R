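# Muscle architecture: storage-corrected volumes, lengths, anatomical
# cross-sectional area (ACSA = volume / length), and body-mass-normalized
# indices assuming isometric scaling (exponents 1, 0.33 and 0.66 for
# volume, length and ACSA).  Normalization is gated per muscle/metric by a
# Pearson correlation test against body mass.

.PRESERVATION_FLAGS <- c("ethanol_short", "ethanol_long", "formalin_month")
.STORAGE_FACTORS <- c(ethanol_short = 1.64, ethanol_long = 2.49,
                      formalin_month = 1.32)

#' Preservation state of a specimen
#'
#' @param flags character vector, subset of `ethanol_short`, `ethanol_long`,
#'   `formalin_month`.  Short- and long-term ethanol storage are mutually
#'   exclusive; formalin exposure can combine with either.
#' @export
preservation_state <- function(flags = character(0)) {
  flags <- unique(as.character(flags))
  bad <- setdiff(flags, .PRESERVATION_FLAGS)
  if (length(bad)) stop("unknown preservation flag(s): ", paste(bad, collapse = ", "))
  if (all(c("ethanol_short", "ethanol_long") %in% flags)) {
    stop("ethanol_short and ethanol_long are mutually exclusive")
  }
  structure(flags, class = "preservation_state")
}

#' Storage-corrected muscle volume
#'
#' Shrinkage corrections compose multiplicatively: x 1.64 for short-term
#' ethanol storage, x 2.49 for long-term ethanol storage, x 1.32 for over a
#' month of formalin exposure.
#'
#' @param raw_volume raw segmented volume, mm^3 (> 0).
#' @param preservation a [preservation_state] or character vector of flags.
#' @return Corrected volume in mm^3.
#' @export
corrected_volume <- function(raw_volume, preservation = character(0)) {
  if (!inherits(preservation, "preservation_state")) {
    preservation <- preservation_state(preservation)
  }
  stopifnot(all(raw_volume > 0))
  raw_volume * prod(.STORAGE_FACTORS[unclass(preservation)], na.rm = TRUE)
}

#' Muscle length from endpoint chains
#'
#' Each belly is measured as the distance between its proximal and distal
#' endpoint (2-point chain) or, for curved muscles, the sum of the two
#' segments through a middle landmark (3-point chain).  Multi-belly muscles
#' report the mean belly length.
#'
#' @param chains a single 2- or 3-row matrix of points (mm), or a list of
#'   such matrices (one per belly).
#' @return Muscle length in mm.
#' @export
muscle_length <- function(chains) {
  if (is.matrix(chains)) chains <- list(chains)
  lens <- vapply(chains, function(ch) {
    ch <- as.matrix(ch)
    if (!(nrow(ch) %in% c(2, 3))) stop("each chain needs 2 or 3 points")
    seg <- sqrt(rowSums((ch[-1, , drop = FALSE] -
                           ch[-nrow(ch), , drop = FALSE])^2))
    if (any(seg < 1e-12)) stop("duplicate consecutive points in chain")
    sum(seg)
  }, numeric(1))
  mean(lens)
}

#' Anatomical cross-sectional area
#'
#' ACSA = total (corrected) volume / total length.
#'
#' @param corrected_volume_mm3 volume in mm^3.
#' @param length_mm length in mm (> 0).
#' @return ACSA in mm^2.
#' @export
acsa <- function(corrected_volume_mm3, length_mm) {
  if (!all(length_mm > 0)) stop("length must be positive")
  corrected_volume_mm3 / length_mm
}

#' Body-mass normalization assuming isometric scaling
#'
#' value / body_mass^exponent with exponents 1 (volume, mm^3/g), 0.33
#' (length, mm/g^0.33) or 0.66 (ACSA, mm^2/g^0.66), used verbatim.
#'
#' @param value quantity to normalize.
#' @param body_mass_g body mass in g (> 0).
#' @param exponent one of 1, 0.33, 0.66.
#' @export
normalize_by_mass <- function(value, body_mass_g, exponent) {
  if (!all(body_mass_g > 0)) stop("body mass must be positive")
  if (length(exponent) != 1 || !(exponent %in% c(1, 0.33, 0.66))) {
    stop("exponent must be one of 1, 0.33, 0.66")
  }
  value / body_mass_g^exponent
}

#' Pearson correlation gate for body-mass normalization
#'
#' Tests for linear correlation between a metric and body mass; the metric
#' is normalized only when significantly correlated (two-sided p below
#' `alpha_level`).
#'
#' @param values metric values (n >= 3, nonzero variance).
#' @param masses paired body masses in g.
#' @param alpha_level significance threshold (default 0.05).
#' @return List with `r`, `p` and logical `normalize`.
#' @export
correlation_gate <- function(values, masses, alpha_level = 0.05) {
  if (length(values) != length(masses)) stop("values and masses must be paired")
  if (length(values) < 3) stop("correlation gate needs at least 3 observations")
  if (stats::var(values) == 0 || stats::var(masses) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(values, masses, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value,
       normalize = ct$p.value < alpha_level)
}

#' Architecture summary for one muscle of one specimen
#'
#' @param raw_volume_mm3 raw segmented volume (mm^3).
#' @param preservation preservation flags (see [preservation_state()]).
#' @param chains endpoint chain(s), see [muscle_length()].
#' @param body_mass_g body mass in g.
#' @return List of class `architecture_result`: `corrected_volume_mm3`,
#'   `length_mm`, `acsa_mm2`, `rel_volume`, `rel_length`, `rel_acsa`.
#' @export
architecture_result <- function(raw_volume_mm3, preservation, chains,
                                body_mass_g) {
  cv <- corrected_volume(raw_volume_mm3, preservation)
  len <- muscle_length(chains)
  a <- acsa(cv, len)
  structure(list(
    corrected_volume_mm3 = cv, length_mm = len, acsa_mm2 = a,
    rel_volume = normalize_by_mass(cv, body_mass_g, 1),
    rel_length = normalize_by_mass(len, body_mass_g, 0.33),
    rel_acsa = normalize_by_mass(a, body_mass_g, 0.66)
  ), class = "architecture_result")
}

#' Architecture table across specimens with the correlation gate
#'
#' Computes corrected volume, length and ACSA per record, then applies the
#' Pearson gate per muscle and metric across specimens: metrics of muscles
#' present in more than two species are normalized by body mass only when
#' significantly correlated with it.  Muscles present in two or fewer
#' species are left unnormalized (gate not applicable).
#'
#' @param records data frame with columns `specimen`, `species`, `muscle`,
#'   `raw_volume_mm3`, `body_mass_g`, logical columns `ethanol_short`,
#'   `ethanol_long`, `formalin_month`, and `length_mm` (pre-measured) or a
#'   list-column `chains`.
#' @param alpha_level Pearson gate significance threshold.
#' @param digits rounding for the `rel_*` report columns (default 3, the
#'   reporting precision used for relative values).
#' @return Long-format data frame: one row per specimen x muscle with
#'   corrected metrics, gate decisions and (where gated in) normalized
#'   values rounded to `digits`.
#' @export
architecture_table <- function(records, alpha_level = 0.05, digits = 3) {
  need <- c("specimen", "species", "muscle", "raw_volume_mm3", "body_mass_g")
  stopifnot(all(need %in% names(records)))
  n <- nrow(records)
  flags <- lapply(seq_len(n), function(i) {
    f <- character(0)
    for (fl in .PRESERVATION_FLAGS) {
      if (!is.null(records[[fl]]) && isTRUE(records[[fl]][i])) f <- c(f, fl)
    }
    f
  })
  cv <- vapply(seq_len(n), function(i) {
    corrected_volume(records$raw_volume_mm3[i], flags[[i]])
  }, numeric(1))
  len <- if (!is.null(records$length_mm)) {
    records$length_mm
  } else {
    vapply(records$chains, muscle_length, numeric(1))
  }
  out <- data.frame(specimen = records$specimen, species = records$species,
                    muscle = records$muscle, body_mass_g = records$body_mass_g,
                    corrected_volume_mm3 = cv, length_mm = len,
                    acsa_mm2 = acsa(cv, len))
  out$rel_volume <- NA_real_
  out$rel_length <- NA_real_
  out$rel_acsa <- NA_real_
  out$gated <- FALSE
  for (m in unique(out$muscle)) {
    idx <- which(out$muscle == m)
    if (length(unique(out$species[idx])) <= 2 || length(idx) < 3) next
    out$gated[idx] <- TRUE
    gates <- list(
      volume = correlation_gate(out$corrected_volume_mm3[idx],
                                out$body_mass_g[idx], alpha_level),
      length = correlation_gate(out$length_mm[idx], out$body_mass_g[idx],
                                alpha_level),
      acsa = correlation_gate(out$acsa_mm2[idx], out$body_mass_g[idx],
                              alpha_level))
    if (gates$volume$normalize) {
      out$rel_volume[idx] <- round(normalize_by_mass(
        out$corrected_volume_mm3[idx], out$body_mass_g[idx], 1), digits)
    }
    if (gates$length$normalize) {
      out$rel_length[idx] <- round(normalize_by_mass(
        out$length_mm[idx], out$body_mass_g[idx], 0.33), digits)
    }
    if (gates$acsa$normalize) {
      out$rel_acsa[idx] <- round(normalize_by_mass(
        out$acsa_mm2[idx], out$body_mass_g[idx], 0.66), digits)
    }
  }
  out
}
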