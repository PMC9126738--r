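#' A/ci gas-exchange curve
#'
#' An ordered set of gas-exchange observations for one leaf. Columns: `ci`
#' intercellular CO2 (Pa), `A` net assimilation (µmol m-2 s-1), `gs`
#' stomatal conductance (mol m-2 s-1), `ca` sample-cell CO2 (Pa), `T_leaf`
#' (degC), `Q` PAR (µmol m-2 s-1), optional `phi_psii` (PSII operating
#' quantum yield, in [0, 1]), and `sequence_index` (acquisition order).
#'
#' @param data data.frame with at least `ci` and `A`; missing optional
#'   columns are filled with `NA`.
#' @param leaf_id,genotype,environment labels.
#' @return An object of class `aci_curve`: the data.frame plus attributes
#'   `leaf_id`, `genotype`, `environment`, `mean_T_leaf`.
#' @export
aci_curve <- function(data, leaf_id = "leaf1", genotype = NA_character_,
                      environment = NA_character_) {
  stopifnot(is.data.frame(data), all(c("ci", "A") %in% names(data)))
  for (col in c("gs", "ca", "T_leaf", "Q", "phi_psii"))
    if (is.null(data[[col]])) data[[col]] <- NA_real_
  if (is.null(data$sequence_index)) data$sequence_index <- seq_len(nrow(data))
  with(data, {
    stopifnot(all(ci >= 0, na.rm = TRUE), all(ca > 0, na.rm = TRUE),
              all(gs >= 0, na.rm = TRUE),
              all(phi_psii >= 0 & phi_psii <= 1, na.rm = TRUE))
  })
  structure(data, class = c("aci_curve", "data.frame"),
            leaf_id = leaf_id, genotype = genotype, environment = environment,
            mean_T_leaf = mean(data$T_leaf, na.rm = TRUE))
}

#' @export
print.aci_curve <- function(x, ...) {
  cat(sprintf("A/ci curve '%s' (%s, %s): %d observations, mean T_leaf %.2f degC\n",
              attr(x, "leaf_id"), attr(x, "genotype"), attr(x, "environment"),
              nrow(x), attr(x, "mean_T_leaf")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Mean leaf temperature of a curve
#' @param curve an `aci_curve`.
#' @return degC; 25 when no temperatures were recorded.
#' @export
mean_t_leaf <- function(curve) {
  m <- attr(curve, "mean_T_leaf")
  if (is.null(m) || is.na(m)) 25 else m
}
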