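#' Generate a potential-origin map
#'
#' Potential origins are the licensed sites where replication may initiate.
#' In the continuous layout every 1-kb block carries a potential origin; in
#' the discrete layout each block independently carries one with
#' probability `1 / mean_spacing`, giving the stated average density (one
#' origin per 2.3 kb by default).
#'
#' @param L Number of 1-kb blocks.
#' @param layout `"continuous"` or `"discrete"`.
#' @param mean_spacing Mean inter-origin spacing in kb (discrete layout);
#'   must be >= 1.
#' @return An object of class `origin_map`: list with `eligible` (logical
#'   vector of length `L`), `layout`, `mean_spacing`.
#' @examples
#' m <- generate_origin_map(1e4, "discrete", 2.3)
#' mean(origin_spacings(m))  # close to 2.3
#' @export
generate_origin_map <- function(L, layout = c("discrete", "continuous"),
                                mean_spacing = 2.3) {
  layout <- match.arg(layout)
  if (L < 1) abort("L must be >= 1")
  if (mean_spacing < 1) abort("mean_spacing must be >= 1 kb")
  eligible <- if (layout == "continuous") {
    rep(TRUE, L)
  } else {
    runif(L) < 1 / mean_spacing
  }
  structure(list(eligible = eligible, layout = layout,
                 mean_spacing = mean_spacing),
            class = "origin_map")
}

#' Nearest-neighbour spacings of a discrete origin map
#'
#' @param map An `origin_map`.
#' @return Numeric vector of distances (kb) between consecutive eligible
#'   blocks.
#' @export
origin_spacings <- function(map) {
  stopifnot(inherits(map, "origin_map"))
  diff(which(map$eligible))
}

#' @export
print.origin_map <- function(x, ...) {
  cat(sprintf("<origin_map> %s, L = %d, %d eligible blocks\n",
              x$layout, length(x$eligible), sum(x$eligible)))
  invisible(x)
}

#' Generate a firing-probability region mask
#'
#' Labels each block of the lattice `IN` (firing probability `Pin`) or
#' `OUT` (`Pout`). Two modes are supported:
#'
#' * `"block"`: exactly `round(theta * L)` blocks are labelled IN, chosen
#'   uniformly at random (used for fitting combing data, where the
#'   segmentation acts at single-block granularity).
#' * `"region"`: contiguous non-overlapping IN regions. Region lengths are
#'   drawn uniformly in `(0, region_length_max]` kb either until their sum
#'   reaches `theta * L` (last region trimmed to hit the target exactly),
#'   or -- when `n_regions` is given -- exactly `n_regions` lengths are
#'   drawn and rescaled so their sum is `theta * L`. Regions are then
#'   placed uniformly at random without overlap. Used for
#'   replication-timing profiles of a structured chromosome.
#'
#' @param L Number of blocks.
#' @param theta Genome fraction labelled IN, in `[0, 1]`.
#' @param mode `"block"` or `"region"`.
#' @param region_length_max Upper bound of the region-length draw, kb.
#' @param n_regions Optional fixed number of regions (region mode).
#' @return An object of class `region_mask`: list with `mask` (logical
#'   vector, TRUE = IN), `mode`, `theta`, and for region mode a `regions`
#'   tibble (`start`, `end`, 0-based half-open kb).
#' @export
generate_region_mask <- function(L, theta, mode = c("block", "region"),
                                 region_length_max = 3000,
                                 n_regions = NULL) {
  mode <- match.arg(mode)
  if (theta < 0 || theta > 1) abort("theta must lie in [0, 1]")
  if (L < 1) abort("L must be >= 1")
  target <- theta * L
  if (mode == "block") {
    k <- round(target)
    mask <- logical(L)
    if (k > 0) mask[sample.int(L, k)] <- TRUE
    return(structure(list(mask = mask, mode = mode, theta = theta,
                          regions = NULL),
                     class = "region_mask"))
  }
  # region mode
  if (region_length_max < 1) abort("region_length_max must be >= 1 kb")
  if (target == 0) {
    lens <- integer(0)
  } else if (is.null(n_regions)) {
    lens <- numeric(0)
    while (sum(lens) < target) {
      lens <- c(lens, runif(1, 0, region_length_max))
    }
    excess <- sum(lens) - target
    lens[length(lens)] <- lens[length(lens)] - excess
  } else {
    lens <- runif(n_regions, 0, region_length_max)
    lens <- lens * target / sum(lens)
  }
  lens <- pmax(1L, as.integer(round(lens)))
  # fix integer-rounding drift on the largest region
  drift <- sum(lens) - round(target)
  if (length(lens) > 0 && drift != 0) {
    i <- which.max(lens)
    lens[i] <- max(1L, lens[i] - drift)
  }
  if (sum(lens) > L) abort("infeasible packing: theta * L exceeds L")
  # uniform non-overlapping placement: distribute the free space among the
  # n + 1 inter-region gaps with a uniform stick-breaking draw
  n <- length(lens)
  mask <- logical(L)
  regions <- tibble(start = integer(0), end = integer(0))
  if (n > 0) {
    lens <- lens[sample.int(n)]
    free <- L - sum(lens)
    cuts <- sort(runif(n, 0, 1))
    gaps <- floor(diff(c(0, cuts)) * free)
    starts <- cumsum(gaps) + cumsum(c(0, head(lens, -1)))
    for (i in seq_len(n)) {
      mask[(starts[i] + 1):(starts[i] + lens[i])] <- TRUE
    }
    regions <- tibble(start = as.integer(starts),
                      end = as.integer(starts + lens))
  }
  structure(list(mask = mask, mode = mode, theta = theta, regions = regions),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %s mode, L = %d, %d IN blocks (theta = %g)\n",
              x$mode, length(x$mask), sum(x$mask), x$theta))
  invisible(x)
}

#' Export IN regions of a mask as BED text
#'
#' Three-column BED (chrom, start, end; 0-based half-open kb coordinates).
#'
#' @param mask A `region_mask`.
#' @param path Output file.
#' @param chrom Chromosome name to print.
#' @return `path`, invisibly.
#' @export
write_mask_bed <- function(mask, path, chrom = "chrS") {
  stopifnot(inherits(mask, "region_mask"))
  r <- rle(mask$mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  df <- data.frame(chrom = chrom, start = starts[keep], end = ends[keep])
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
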