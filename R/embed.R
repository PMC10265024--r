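#' Embed scaled call features into a 2-D acoustic trait space
#'
#' Reduces the scaled per-call feature vectors to two dimensions with exact
#' t-distributed stochastic neighbour embedding (t-SNE), so that acoustically
#' similar calls lie close together. All calls that will later be compared
#' (every individual, every block) must be embedded jointly in a single call
#' to this function: coordinates from separate embeddings are not
#' commensurable.
#'
#' The implementation is the exact O(n^2) gradient-descent algorithm
#' (Gaussian input affinities at a fixed perplexity, Student-t output
#' kernel, early exaggeration, adaptive gains). Given the same input and
#' seed the coordinates are bit-reproducible.
#'
#' @param table Scaled feature table (see [scale_features()]).
#' @param cols Feature columns; defaults to the canonical 17.
#' @param perplexity t-SNE perplexity; the table must have more than
#'   `3 * perplexity` rows.
#' @param iterations Gradient-descent iterations.
#' @param seed Integer seed for the random initial layout.
#' @param learning_rate Gradient-descent learning rate.
#' @return The input table with `dim1`, `dim2` coordinate columns appended;
#'   embedding parameters are recorded in the `"embedding"` attribute.
#' @export
embed_features <- function(table, cols = intersect(all_feature_names(),
                                                   names(table)),
                           perplexity = 30, iterations = 1000, seed = 1L,
                           learning_rate = 200) {
  n <- nrow(table)
  min_rows <- floor(3 * perplexity) + 1
  if (n < min_rows)
    stop(sprintf("too few rows (%d) for perplexity %.1f: need at least %d",
                 n, perplexity, min_rows))
  X <- as.matrix(table[cols])
  if (!all(is.finite(X))) stop("non-finite feature values")
  Y0 <- with_seed(seed, matrix(rnorm(2L * n, sd = 1e-4), ncol = 2L))
  Y <- .tsne_exact(X, Y0, perplexity, as.integer(iterations),
                   learning_rate, 12, 250L)
  table$dim1 <- Y[, 1]
  table$dim2 <- Y[, 2]
  attr(table, "embedding") <- list(method = "tsne_exact",
                                   perplexity = perplexity,
                                   iterations = iterations, seed = seed,
                                   learning_rate = learning_rate)
  table
}
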