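#' Default cortical region set
#'
#' The 11 Brodmann-area labels used throughout, ordered anterior to posterior.
#' The rank of a region along this axis is its position in the vector; regional
#' expression gradients are parameterized as log2 change per rank step.
#'
#' @return Character vector of 11 region labels in anterior-to-posterior order.
#' @export
default_regions <- function() {
  c("BA9", "BA44/45", "BA24", "BA4/6", "BA38", "BA3/1/2/5",
    "BA41/42/22", "BA20/37", "BA7", "BA39/40", "BA17")
}

#' Cortical lobe of each default region
#'
#' Used as (part of) the grouping key for sample outlier detection.
#'
#' @param regions character vector of region labels.
#' @return Character vector of lobes ("frontal", "temporal", "parietal",
#'   "occipital"); unknown labels map to `"other"`.
#' @export
region_lobe <- function(regions) {
  map <- c("BA9" = "frontal", "BA44/45" = "frontal", "BA24" = "frontal",
           "BA4/6" = "frontal", "BA38" = "temporal", "BA41/42/22" = "temporal",
           "BA20/37" = "temporal", "BA3/1/2/5" = "parietal", "BA7" = "parietal",
           "BA39/40" = "parietal", "BA17" = "occipital")
  out <- unname(map[regions])
  out[is.na(out)] <- "other"
  out
}

#' Enumerate unique region pairs
#'
#' All unordered pairs of distinct regions, each stored in canonical
#' (anterior-to-posterior rank) order. With the default 11 regions this yields
#' 55 pairs.
#'
#' @param regions ordered character vector of region labels (anterior first).
#' @return data.frame with columns `region_a`, `region_b` (canonical order:
#'   `region_a` is the more anterior) and `pair` (a stable `"a|b"` key).
#' @export
region_pairs <- function(regions = default_regions()) {
  stopifnot(!anyDuplicated(regions), length(regions) >= 2)
  idx <- utils::combn(length(regions), 2)
  out <- data.frame(region_a = regions[idx[1, ]],
                    region_b = regions[idx[2, ]],
                    stringsAsFactors = FALSE)
  out$pair <- paste(out$region_a, out$region_b, sep = "|")
  out
}

#' Canonicalize a region pair
#'
#' @param region_a,region_b distinct region labels.
#' @param regions ordered region vector defining the canonical order.
#' @return list with `region_a`, `region_b` (rank order), `pair` key.
#' @export
pair_key <- function(region_a, region_b, regions = default_regions()) {
  if (region_a == region_b) stop("a region pair needs two distinct regions")
  ra <- match(region_a, regions); rb <- match(region_b, regions)
  if (is.na(ra) || is.na(rb)) stop("unknown region label")
  if (ra > rb) { tmp <- region_a; region_a <- region_b; region_b <- tmp }
  list(region_a = region_a, region_b = region_b,
       pair = paste(region_a, region_b, sep = "|"))
}

# Deterministic per-stage / per-pair seed derivation: fold a key string into
# the master seed, keeping the result a valid 32-bit R integer.
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- 0
  for (code in utf8ToInt(as.character(key))) h <- (h * 31 + code) %% 2147483647
  as.integer((abs(master) * 48271 + h) %% 2147483647)
}
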