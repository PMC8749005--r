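# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Squared Euclidean distances between rows of X (and rows of Y if given),
# computed through BLAS; clamped at zero against roundoff.
row_sqdist <- function(X, Y = NULL) {
  if (is.null(Y)) {
    G <- tcrossprod(X)
    n2 <- diag(G)
    D2 <- outer(n2, n2, "+") - 2 * G
  } else {
    G <- tcrossprod(X, Y)
    D2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
  }
  D2[D2 < 0] <- 0
  D2
}

row_dist <- function(X, Y = NULL) sqrt(row_sqdist(X, Y))

# Connected components of an undirected adjacency pattern (logical matrix).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      frontier <- i
      comp[i] <- cur
      while (length(frontier)) {
        nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
        nb <- nb[comp[nb] == 0L]
        comp[nb] <- cur
        frontier <- nb
      }
    }
  }
  comp
}

#' Procrustes RMSD between two configurations
#'
#' Root-mean-square deviation after least-squares superimposition
#' (translation, rotation, and optionally uniform scaling) of `Y` onto
#' `X`. Used to compare embedding output with a known configuration.
#'
#' @param X,Y matrices of matching dimension (points x coordinates).
#' @param scale allow uniform scaling (default TRUE).
#' @return RMSD after alignment (scalar).
#' @export
procrustes_rmsd <- function(X, Y, scale = TRUE) {
  stopifnot(all(dim(X) == dim(Y)))
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  g <- if (scale) sum(s$d) / sum(Yc^2) else 1
  fit <- g * Yc %*% R
  sqrt(mean(rowSums((Xc - fit)^2)))
}
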