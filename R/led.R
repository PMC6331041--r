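#' Euclidean distance between two expression profiles
#'
#' @param p,q numeric vectors of equal length (relative abundances over the
#'   same tissues, in the same order).
#' @return sqrt(sum((p - q)^2)), a non-negative scalar.
#' @examples
#' euclideanDistance(c(1, 0), c(0, 1))  # sqrt(2)
#' @export
euclideanDistance <- function(p, q) {
  if (length(p) != length(q)) {
    stop(sprintf("profile length mismatch: %d vs %d", length(p), length(q)))
  }
  sqrt(sum((p - q)^2))
}

#' Pairwise profile distances for aligned ortholog triples
#'
#' Row i of each matrix is the profile of the i-th triple's member in that
#' species; rows must be aligned across the three matrices.
#'
#' @param px,py,pz numeric matrices (triples x tissues) of profiles.
#' @return data.frame with columns `e_xy`, `e_xz`, `e_yz`.
#' @export
pairwiseProfileDistances <- function(px, py, pz) {
  stopifnot(all(dim(px) == dim(py)), all(dim(px) == dim(pz)))
  data.frame(
    e_xy = sqrt(rowSums((px - py)^2)),
    e_xz = sqrt(rowSums((px - pz)^2)),
    e_yz = sqrt(rowSums((py - pz)^2))
  )
}

#' Lineage-specific expression divergence from a distance triple
#'
#' Decomposes the three pairwise expression distances of an ortholog triple
#' into per-lineage branch lengths of the unrooted three-taxon tree:
#' \deqn{LED_X = (E_{X,Y} + E_{X,Z} - E_{Y,Z}) / 2} and cyclically for Y and
#' Z. The three additivity identities
#' `led_x + led_y = e_xy` etc. hold by construction.
#'
#' Distances computed from actual profile vectors are Euclidean, hence
#' metric, and all branch lengths are then non-negative. Tiny negative values
#' (magnitude at most `tol`, floating-point artifacts) are clamped to zero;
#' larger negatives indicate a non-metric input and raise an error.
#'
#' @param distances data.frame (or list) with numeric columns `e_xy`, `e_xz`,
#'   `e_yz`; vectorized over rows.
#' @param tol clamp tolerance for negative branch lengths; default 1e-12.
#' @return data.frame with columns `led_x`, `led_y`, `led_z`.
#' @examples
#' computeLED(data.frame(e_xy = sqrt(2), e_xz = sqrt(2), e_yz = 0))
#' @export
computeLED <- function(distances, tol = 1e-12) {
  e_xy <- distances$e_xy
  e_xz <- distances$e_xz
  e_yz <- distances$e_yz
  stopifnot(length(e_xy) == length(e_xz), length(e_xy) == length(e_yz))
  if (any(e_xy < 0 | e_xz < 0 | e_yz < 0)) {
    stop("pairwise distances must be non-negative")
  }
  led <- data.frame(
    led_x = 0.5 * (e_xy + e_xz - e_yz),
    led_y = 0.5 * (e_xy + e_yz - e_xz),
    led_z = 0.5 * (e_xz + e_yz - e_xy)
  )
  worst <- min(led$led_x, led$led_y, led$led_z, 0)
  if (worst < -tol) {
    stop(sprintf(
      "triangle inequality violated (branch length %g): input is not metric",
      worst
    ))
  }
  led[led < 0] <- 0
  led
}

#' Per-branch generation scaling constants
#'
#' Converts a generation time (days to anthesis, i.e. days to flowering) and
#' a divergence age (millions of years from the internal node of the
#' three-taxon tree) into the total number of generations elapsed along a
#' species' branch: (365 / days_to_anthesis) * divergence_my * 1e6.
#'
#' @param species character vector of species identifiers.
#' @param days_to_anthesis days per generation; strictly positive.
#' @param divergence_my branch age in millions of years; strictly positive.
#' @return data.frame with columns `species`, `days_to_anthesis`,
#'   `divergence_my`, `generations_per_year`, `total_generations`.
#' @examples
#' branchScale("B_distachyon", 35, 50)  # ~5.2143e8 generations
#' @export
branchScale <- function(species, days_to_anthesis, divergence_my) {
  stopifnot(
    length(species) == length(days_to_anthesis),
    length(species) == length(divergence_my),
    all(days_to_anthesis > 0), all(divergence_my > 0)
  )
  gpy <- 365 / days_to_anthesis
  data.frame(
    species = as.character(species),
    days_to_anthesis = days_to_anthesis,
    divergence_my = divergence_my,
    generations_per_year = gpy,
    total_generations = gpy * divergence_my * 1e6
  )
}

#' Scale LED branch lengths by total generations per branch
#'
#' Divides each gene's branch length by the total number of generations
#' elapsed along that lineage, yielding LED per generation. Gene order is
#' preserved.
#'
#' @param led data.frame with columns `led_x`, `led_y`, `led_z`.
#' @param scales data.frame from [branchScale()] with exactly three rows, in
#'   species x, y, z order.
#' @return data.frame with columns `led_x`, `led_y`, `led_z` (scaled).
#' @export
scalePerGeneration <- function(led, scales) {
  if (!is.data.frame(scales) || nrow(scales) != 3L ||
      !"total_generations" %in% names(scales) ||
      anyNA(scales$total_generations)) {
    stop("'scales' must provide total_generations for all three species")
  }
  data.frame(
    led_x = led$led_x / scales$total_generations[1L],
    led_y = led$led_y / scales$total_generations[2L],
    led_z = led$led_z / scales$total_generations[3L]
  )
}
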