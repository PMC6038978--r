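#' OSEM reconstruction of a SPECT projection set
#'
#' Ordered-subsets expectation maximization with the package's parallel-beam
#' rotate-and-sum projector/backprojector pair, the protocol's 4 subsets and
#' 30 iterations by default, and no scatter or attenuation correction.
#' Views are interleaved across subsets (view `v` belongs to subset
#' `v mod subsets`), initialization is a uniform positive volume, and voxels
#' with zero sensitivity are held at zero. The multiplicative update keeps
#' the volume nonnegative by construction.
#'
#' @param projections a `projection_set`.
#' @param subsets number of ordered subsets; must divide the view count.
#' @param iterations number of full iterations (every subset visited once
#'   per iteration).
#' @param callback optional `function(volume, iteration)` invoked after each
#'   full iteration (e.g. to track convergence against a known phantom).
#' @return object of class `recon_volume`: list with `voxels` (x,y,z array),
#'   `subsets`, `iterations`.
#' @export
osem_reconstruct <- function(projections, subsets = 4L, iterations = 30L,
                             callback = NULL) {
  stopifnot(inherits(projections, "projection_set"))
  views <- projections$views
  n_views <- dim(views)[1]
  n <- dim(views)[2]
  n_slices <- dim(views)[3]
  if (n_views %% subsets != 0)
    mibg_error("IndivisibleSubsets",
               sprintf("%d views not divisible into %d subsets",
                       n_views, subsets))
  eps <- 1e-12
  subset_views <- lapply(seq_len(subsets), function(s)
    which((seq_len(n_views) - 1L) %% subsets == s - 1L))
  A_sub <- vector("list", subsets)
  Y_sub <- vector("list", subsets)
  sens <- vector("list", subsets)
  for (s in seq_len(subsets)) {
    vs <- subset_views[[s]]
    A_sub[[s]] <- projector_matrix(n, projections$angles_deg[vs])
    sens[[s]] <- as.numeric(Matrix::colSums(A_sub[[s]]))
    y <- aperm(views[vs, , , drop = FALSE], c(2, 1, 3))
    Y_sub[[s]] <- matrix(y, n * length(vs), n_slices)
  }
  X <- matrix(1, n * n, n_slices)
  dead <- lapply(sens, function(s) s < eps)
  for (it in seq_len(iterations)) {
    for (s in seq_len(subsets)) {
      Fp <- as.matrix(A_sub[[s]] %*% X)
      ratio <- Y_sub[[s]] / pmax(Fp, eps)
      bp <- as.matrix(Matrix::crossprod(A_sub[[s]], ratio))
      X <- X * bp / pmax(sens[[s]], eps)
      X[dead[[s]], ] <- 0
    }
    if (!is.null(callback))
      callback(array(X, dim = c(n, n, n_slices)), it)
  }
  structure(list(voxels = array(X, dim = c(n, n, n_slices)),
                 subsets = subsets, iterations = iterations),
            class = "recon_volume")
}

# Poisson log-likelihood of projections given a volume (monitoring aid).
projection_loglik <- function(projections, volume) {
  vox <- if (is.list(volume)) volume$voxels else volume
  n <- dim(vox)[1]
  A <- projector_matrix(n, projections$angles_deg)
  lam <- as.matrix(A %*% matrix(vox, n * n, dim(vox)[3]))
  y <- matrix(aperm(projections$views, c(2, 1, 3)), length(lam) / dim(vox)[3],
              dim(vox)[3])
  lam <- pmax(lam, 1e-12)
  sum(y * log(lam) - lam)
}
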