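# Individualized reclassification of valence ratings into negative / neutral /
# positive categories by exhaustive threshold search.

#' Reclassify one participant's valence ratings
#'
#' Searches all ordered threshold pairs `(t1, t2)` with `1 <= t1 < t2 <= 8`
#' on the 1-9 rating scale. A video is negative when `rating <= t1`, neutral
#' when `t1 < rating <= t2`, positive when `rating > t2`. The selected pair
#' minimizes the total pairwise difference in category size
#' `|n_neg - n_neu| + |n_neg - n_pos| + |n_neu - n_pos|`; ties are broken by
#' proximity to the a-priori pair `(3, 6)` (L1 distance), then
#' lexicographically.
#'
#' @param ratings integer vector of ratings in 1..9 (>= 3 videos).
#' @param videos optional video identifiers (defaults to `seq_along(ratings)`).
#' @return List with `t1`, `t2`, `category` (factor negative/neutral/positive
#'   per video), `sizes` (named counts) and `objective`.
#' @export
reclassify_valence <- function(ratings, videos = seq_along(ratings)) {
  if (length(ratings) < 3L) stop("need ratings for at least 3 videos")
  if (any(!ratings %in% 1:9)) stop("ratings must be integers in 1..9")
  counts <- tabulate(ratings, nbins = 9)
  best <- NULL
  for (t1 in 1:7) {
    for (t2 in (t1 + 1):8) {
      n_neg <- sum(counts[1:t1])
      n_neu <- sum(counts[(t1 + 1):t2])
      n_pos <- sum(counts[(t2 + 1):9])
      obj <- abs(n_neg - n_neu) + abs(n_neg - n_pos) + abs(n_neu - n_pos)
      cand <- list(t1 = t1, t2 = t2, obj = obj,
                   prior_dist = abs(t1 - 3) + abs(t2 - 6))
      if (is.null(best) ||
          obj < best$obj ||
          (obj == best$obj && cand$prior_dist < best$prior_dist) ||
          (obj == best$obj && cand$prior_dist == best$prior_dist &&
             (t1 < best$t1 || (t1 == best$t1 && t2 < best$t2)))) {
        best <- cand
      }
    }
  }
  category <- factor(ifelse(ratings <= best$t1, "negative",
                            ifelse(ratings <= best$t2, "neutral", "positive")),
                     levels = c("negative", "neutral", "positive"))
  sizes <- table(category)
  list(t1 = best$t1, t2 = best$t2,
       category = stats::setNames(category, videos),
       sizes = c(negative = unname(sizes["negative"]),
                 neutral = unname(sizes["neutral"]),
                 positive = unname(sizes["positive"])),
       objective = best$obj)
}
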