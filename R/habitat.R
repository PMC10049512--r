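#' Default threat specification
#'
#' Threat layers with relative weights, maximum impact distances and decay
#' kinds. Point-like threats (settlements, mining) decay exponentially; the
#' linear road network decays linearly. All three knobs are plain data-frame
#' columns and can be edited freely.
#'
#' @return data.frame with columns `name`, `weight`, `max_dist` (m), `decay`.
#' @export
default_threats <- function() {
  data.frame(
    name = c("settlement", "mining", "road"),
    weight = c(1.0, 0.8, 0.6),
    max_dist = c(5000, 3000, 2000),
    decay = c("exponential", "exponential", "linear"),
    stringsAsFactors = FALSE
  )
}

#' Default habitat suitability and sensitivity table
#'
#' Per land-cover class: habitat suitability H in [0,1] (forest, grassland,
#' shrubland, wetland and water are habitat; cultivated land is semi-habitat
#' at H = 0.3; artificial surfaces and bare land are non-habitat) and one
#' sensitivity column per threat, all in [0,1].
#'
#' @param semi_habitat suitability assigned to cultivated (semi-habitat) land.
#' @return data.frame with columns `class`, `code`, `habitat`, and one column
#'   per threat in [default_threats()].
#' @export
default_sensitivity <- function(semi_habitat = 0.3) {
  cls <- landcover_classes()
  data.frame(
    class = names(cls),
    code = unname(cls),
    habitat = c(semi_habitat, 1.0, 0.7, 0.8, 0.9, 1.0, 0.0, 0.1),
    settlement = c(0.4, 0.7, 0.6, 0.6, 0.9, 0.8, 0.0, 0.1),
    mining = c(0.3, 0.6, 0.5, 0.5, 0.8, 0.7, 0.0, 0.1),
    road = c(0.3, 0.6, 0.5, 0.4, 0.6, 0.5, 0.0, 0.1),
    stringsAsFactors = FALSE
  )
}

#' Habitat degradation from threat layers
#'
#' Cellwise degradation
#' \deqn{D(x) = \sum_r \frac{w_r}{\sum w} \, i_r(x) \, S_{j(x),r}}
#' where the impact kernel is \eqn{i_r = \max(0, 1 - d/d_{max})} for linear
#' decay and \eqn{i_r = \exp(-2.99\, d / d_{max})}, clipped to 0 beyond
#' \eqn{d_{max}}, for exponential decay; `d` is the Euclidean distance to the
#' nearest cell of threat `r`.
#'
#' @param stack `landscape_stack` carrying the threat masks.
#' @param threats data.frame as [default_threats()].
#' @param sens sensitivity table as [default_sensitivity()].
#' @return continuous `eco_grid` of degradation D >= 0.
#' @export
habitat_degradation <- function(stack, threats = default_threats(),
                                sens = default_sensitivity()) {
  lc <- stack$landcover
  threat_cols <- setdiff(names(sens), c("class", "code", "habitat"))
  missing <- setdiff(intersect(threat_cols, threats$name), names(stack$threats))
  if (length(missing))
    stop("configuration error: threat(s) named in sensitivity table absent from stack: ",
         paste(missing, collapse = ", "))
  wsum <- sum(threats$weight)
  D <- matrix(0, nrow(lc$values), ncol(lc$values))
  code_order <- order(sens$code)
  for (i in seq_len(nrow(threats))) {
    nm <- threats$name[i]
    if (!nm %in% names(stack$threats))
      stop("configuration error: threat '", nm, "' has no mask in the stack")
    d <- distance_to(stack$threats[[nm]])$values
    dmax <- threats$max_dist[i]
    ir <- if (threats$decay[i] == "linear") {
      pmax(0, 1 - d / dmax)
    } else {
      ifelse(d >= dmax, 0, exp(-2.99 * d / dmax))
    }
    # sensitivity of each cell's land-cover class to this threat
    s_by_code <- sens[[nm]][code_order]
    S <- matrix(s_by_code[lc$values], nrow(lc$values), ncol(lc$values))
    D <- D + (threats$weight[i] / wsum) * ir * S
  }
  D[is.na(lc$values)] <- NA
  grid_like(lc, D, band_kind = "continuous")
}

#' Habitat quality index
#'
#' The half-saturation habitat quality model
#' \deqn{Q = H_j \left[ 1 - \frac{D^z}{D^z + k^z} \right]}
#' so that Q equals the class suitability where degradation is zero and
#' halves (for H = 1) where D equals the half-saturation constant k.
#'
#' @param D continuous degradation `eco_grid`.
#' @param landcover categorical `eco_grid`.
#' @param sens sensitivity table (supplies H per class).
#' @param k half-saturation constant, > 0.
#' @param z exponent, > 0.
#' @return continuous `eco_grid` of quality in [0, max H].
#' @export
habitat_quality <- function(D, landcover, sens = default_sensitivity(),
                            k = 0.5, z = 2.5) {
  stopifnot(k > 0, z > 0)
  check_aligned(D, landcover)
  code_order <- order(sens$code)
  h_by_code <- sens$habitat[code_order]
  H <- matrix(h_by_code[landcover$values], nrow(D$values), ncol(D$values))
  dz <- D$values^z
  Q <- H * (1 - dz / (dz + k^z))
  Q[is.na(D$values) | is.na(landcover$values)] <- NA
  grid_like(D, Q, band_kind = "continuous")
}

#' Classify habitat quality into ordered levels
#'
#' Fisher-Jenks natural-breaks classification into `n_classes` levels,
#' level `n_classes` being the highest quality.
#'
#' @param Q continuous quality `eco_grid`.
#' @param n_classes number of levels (default 5).
#' @return categorical `eco_grid` of levels 1..n_classes.
#' @export
classify_quality <- function(Q, n_classes = 5) {
  jenks_classify(Q, n_classes = n_classes)
}

#' Extract ecological sources
#'
#' 8-connected patches of the top quality level whose area strictly exceeds
#' `min_area_km2`, relabelled 1..n in order of decreasing area.
#'
#' @param levels categorical `eco_grid` from [classify_quality()].
#' @param min_area_km2 strict lower area bound (default 2).
#' @return `patch_set` of sources (possibly empty).
#' @export
extract_sources <- function(levels, min_area_km2 = 2.0) {
  top <- max(levels$values, na.rm = TRUE)
  ps <- label_patches(levels, foreground = top, connectivity = 8)
  keep <- which(ps$areas > min_area_km2)
  keep <- keep[order(ps$areas[keep], decreasing = TRUE)]
  relabel_patches(ps, keep)
}

# Keep only the listed patch ids, relabelled 1..length(keep) in the given
# order.
relabel_patches <- function(ps, keep) {
  lab <- ps$labels$values
  new <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) new[lab == keep[i]] <- i
  new[is.na(lab)] <- NA
  structure(
    list(labels = grid_like(ps$labels, new, band_kind = "categorical"),
         areas = stats::setNames(unname(ps$areas[keep]), seq_along(keep)),
         connectivity = ps$connectivity),
    class = "patch_set"
  )
}
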