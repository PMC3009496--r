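#' Best-Jaccard recovery of planted modules
#'
#' For each planted module, the maximum Jaccard index against any detected
#' module; summarizes how well a clustering recovers a known ground truth.
#'
#' @param clustering `hunter_clustering` or list of character vectors.
#' @param truth list of planted member vectors.
#' @return numeric vector, one best-Jaccard per planted module.
#' @export
best_jaccard <- function(clustering, truth) {
  mods <- if (inherits(clustering, "hunter_clustering")) clustering$modules else clustering
  vapply(truth, function(tr) {
    if (!length(mods)) return(0)
    max(vapply(mods, function(m)
      length(intersect(m, tr)) / length(union(m, tr)), 0))
  }, 0)
}
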