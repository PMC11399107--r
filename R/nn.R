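# Numerical core for the geometric network: parameter containers, radial
# basis encodings, forward pass and hand-derived reverse-mode gradients.
# All learnable maps are dense layers stored as (input x output) matrices so
# that Y = X %*% W + b; the architecture is small enough that base R matrix
# ops on one CPU train the synthetic corpus in minutes.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

lrelu <- function(x) pmax(x, 0) + 0.05 * pmin(x, 0)
lrelu_grad <- function(x) ifelse(x > 0, 1, 0.05)

#' Model configuration
#'
#' All tunables of the network in one place. `mode` selects which readout
#' channels are active: `"full"` uses all four point groups plus shape
#' features, `"groove"` only the major/minor base-edge groups (no backbone
#' convolutions, no shape), `"shape"` only the phosphate/sugar groups plus
#' shape features, `"full_seqinfo"` additionally re-attaches the DNA
#' sequence one-hots to the helix points.
#'
#' @param mode One of `"full"`, `"groove"`, `"shape"`, `"full_seqinfo"`.
#' @param embed_dim Width of atom/point embeddings.
#' @param n_protein_layers Rounds of spatial message passing on the protein
#'   graph.
#' @param r_bipartite Protein-atom to helix-point edge cutoff (Angstrom).
#' @param n_rbf Number of Gaussian radial basis functions on (0, cutoff].
#' @param conv1d_kernel Odd kernel width of the 1D convolutions along the
#'   pair axis (same-length zero padding).
#' @param n_conv1d_layers Number of 1D convolution layers before the 4-way
#'   head.
#' @param conv1d_channels Channels of the 1D convolutions.
#' @param r_graph Protein-graph edge cutoff (Angstrom).
#' @param max_degree Protein-graph per-vertex neighbour cap.
#' @param seed Seed for parameter initialization.
#' @return List of class `specnet_config`.
#' @export
specnet_config <- function(mode = c("full", "groove", "shape", "full_seqinfo"),
                           embed_dim = 32L, n_protein_layers = 3L,
                           r_bipartite = 5.0, n_rbf = 16L,
                           conv1d_kernel = 5L, n_conv1d_layers = 2L,
                           conv1d_channels = 32L,
                           r_graph = 4.0, max_degree = 16L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(r_bipartite > 0, embed_dim >= 1, n_rbf >= 1,
            n_protein_layers >= 1, n_conv1d_layers >= 1)
  if (conv1d_kernel %% 2 != 1) {
    stop("conv1d_kernel must be odd (position-preserving padding)")
  }
  structure(list(
    mode = mode, embed_dim = as.integer(embed_dim),
    n_protein_layers = as.integer(n_protein_layers),
    r_bipartite = r_bipartite, n_rbf = as.integer(n_rbf),
    conv1d_kernel = as.integer(conv1d_kernel),
    n_conv1d_layers = as.integer(n_conv1d_layers),
    conv1d_channels = as.integer(conv1d_channels),
    r_graph = r_graph, max_degree = as.integer(max_degree),
    seed = as.integer(seed)
  ), class = "specnet_config")
}

config_active_groups <- function(config) {
  switch(config$mode,
         groove = c("major", "minor"),
         shape = c("phosphate", "sugar"),
         GROUP_ORDER)
}

config_has_shape <- function(config) config$mode != "groove"
config_has_seq <- function(config) config$mode == "full_seqinfo"

# Flatten width: 11 point blocks of 2d (mean||max) plus optional shape/seq.
config_flat_width <- function(config) {
  22L * config$embed_dim + 4L * config_has_shape(config) +
    4L * config_has_seq(config)
}

rbf_expand <- function(d, cutoff, K) {
  centers <- seq(cutoff / K, cutoff, length.out = K)
  sigma <- cutoff / K
  exp(-(outer(d, centers, "-"))^2 / (2 * sigma^2))
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout)
}

# Initialize all parameters. The 4-way head is zero-initialized so an
# untrained model predicts exactly uniform columns.
init_params <- function(config) {
  d <- config$embed_dim
  K <- config$n_rbf
  Fdim <- atom_feature_dim()
  k <- config$conv1d_kernel
  C <- config$conv1d_channels
  Win <- config_flat_width(config)
  with_seed(config$seed, {
    p <- list(W_emb = glorot(Fdim, d), b_emb = rep(0, d))
    for (l in seq_len(config$n_protein_layers)) {
      p[[paste0("W_msg", l)]] <- glorot(d + K, d)
      p[[paste0("b_msg", l)]] <- rep(0, d)
      p[[paste0("W_upd", l)]] <- glorot(2 * d, d)
      p[[paste0("b_upd", l)]] <- rep(0, d)
    }
    for (g in GROUP_ORDER) {
      p[[paste0("W_grp_", g)]] <- glorot(d + K + 2, d)
      p[[paste0("b_grp_", g)]] <- rep(0, d)
    }
    nin <- Win
    for (cl in seq_len(config$n_conv1d_layers)) {
      p[[paste0("W_conv", cl)]] <- glorot(nin * k, C)
      p[[paste0("b_conv", cl)]] <- rep(0, C)
      nin <- C
    }
    p$W_head <- matrix(0, C, 4)
    p$b_head <- rep(0, 4)
    p
  })
}

# --- tensorized per-complex input ------------------------------------------

# Build the mean/max aggregation bookkeeping for one set of bipartite edges:
# an index matrix (points x max-degree) into edge rows, 0-padded.
edge_index_matrix <- function(point_of_edge, n_points) {
  if (!length(point_of_edge)) {
    return(list(IDX = matrix(0L, n_points, 0), cnt = rep(0L, n_points)))
  }
  ord <- order(point_of_edge)
  ps <- point_of_edge[ord]
  r <- rle(ps)
  cnt <- rep(0L, n_points)
  cnt[r$values] <- r$lengths
  IDX <- matrix(0L, n_points, max(r$lengths))
  IDX[cbind(ps, sequence(r$lengths))] <- ord
  list(IDX = IDX, cnt = cnt)
}

# Precompute everything the forward pass needs for one complex under one
# configuration: protein graph tensors, bipartite edges per group with
# geometric features, flatten index maps, shape and sequence blocks.
precompute_inputs <- function(complex, config,
                              template = sym_helix_template()) {
  graph <- build_protein_graph(complex$protein_atoms,
                               r_graph = config$r_graph,
                               max_degree = config$max_degree)
  helix <- build_sym_helix(complex, template = template,
                           seq_info = config_has_seq(config))
  A <- nrow(graph$atoms)
  d <- config$embed_dim
  # directed protein edges (both orientations)
  e <- graph$edges
  src <- c(e[, 1], e[, 2])
  dst <- c(e[, 2], e[, 1])
  pe_rbf <- rbf_expand(c(graph$lengths, graph$lengths), config$r_graph,
                       config$n_rbf)
  deg <- tabulate(dst, nbins = A)

  XYZ <- as.matrix(graph$atoms[, c("x", "y", "z")])
  pts <- helix$points
  n_pairs <- helix$n_pairs
  groups <- list()
  for (g in GROUP_ORDER) {
    sel <- pts$group == g & pts$present
    pg <- pts[sel, , drop = FALSE]
    n_pts <- nrow(pg)
    if (n_pts && A) {
      P <- as.matrix(pg[, c("x", "y", "z")])
      d2 <- outer(rowSums(XYZ^2), rowSums(P^2), "+") - 2 * XYZ %*% t(P)
      d2[d2 < 0] <- 0
      hit <- which(d2 <= config$r_bipartite^2 + 1e-9, arr.ind = TRUE)
    } else {
      hit <- matrix(integer(0), 0, 2)
    }
    if (nrow(hit)) {
      ea <- hit[, 1]; ep <- hit[, 2]
      dvec <- P[ep, , drop = FALSE] - XYZ[ea, , drop = FALSE]
      dist <- sqrt(rowSums(dvec^2))
      dist[dist < 1e-9] <- 1e-9
      dir <- dvec / dist
      nrm <- as.matrix(pg[ep, c("nx", "ny", "nz"), drop = FALSE])
      axs <- as.matrix(pg[ep, c("ax", "ay", "az"), drop = FALSE])
      cos_n <- rowSums(dir * nrm)
      cos_n[!is.finite(cos_n)] <- 0
      cos_a <- rowSums(dir * axs)
      geo <- cbind(rbf_expand(dist, config$r_bipartite, config$n_rbf),
                   cos_n, cos_a)
    } else {
      ea <- integer(0); ep <- integer(0)
      geo <- matrix(0, 0, config$n_rbf + 2)
    }
    agg <- edge_index_matrix(ep, n_pts)
    # flatten placement: block index by fixed (group, slot) order
    block0 <- c(major = 0L, minor = 4L, phosphate = 7L, sugar = 9L)[g]
    groups[[g]] <- list(
      n_pts = n_pts, edge_atom = ea, edge_point = ep, geo = geo,
      IDX = agg$IDX, cnt = agg$cnt,
      flat_row = pg$pair_index + 1L,
      flat_col0 = (block0 + pg$slot - 1L) * 2L * d
    )
  }
  shape_block <- if (config_has_shape(config)) helix$shape_z else NULL
  seq_block <- if (config_has_seq(config)) helix$seq else NULL
  list(graph = graph, helix = helix, X = graph$features,
       src = src, dst = dst, pe_rbf = pe_rbf, deg = deg,
       groups = groups, shape = shape_block, seq = seq_block,
       n_pairs = n_pairs, atom_ids = graph$atoms$atom_id)
}

# Aggregate edge messages per point: mean || max (zero vectors for points
# with no edges). Returns the concatenated matrix plus argmax bookkeeping.
aggregate_mean_max <- function(B, g) {
  d <- ncol(B)
  n <- g$n_pts
  PM <- matrix(0, n, d)
  PX <- matrix(0, n, d)
  AM <- matrix(0L, n, d)
  if (length(g$edge_point)) {
    rs <- rowsum(B, group = g$edge_point)
    rows <- as.integer(rownames(rs))
    PM[rows, ] <- rs / pmax(g$cnt[rows], 1L)
    cur <- matrix(-Inf, n, d)
    for (j in seq_len(ncol(g$IDX))) {
      ej <- g$IDX[, j]
      valid <- ej > 0L
      if (!any(valid)) next
      cand <- matrix(-Inf, n, d)
      cand[valid, ] <- B[ej[valid], , drop = FALSE]
      better <- cand > cur
      if (any(better)) {
        cur[better] <- cand[better]
        AM[better] <- rep(ej, d)[better]
      }
    }
    cur[!is.finite(cur)] <- 0
    PX <- cur
  }
  list(PM = PM, PX = PX, AM = AM)
}

unfold1d <- function(Zp, k, n) {
  do.call(cbind, lapply(seq_len(k), function(w) Zp[w:(w + n - 1), , drop = FALSE]))
}

softmax_rows <- function(L) {
  m <- apply(L, 1, max)
  E <- exp(L - m)
  E / rowSums(E)
}

# Full forward pass. `mask` is an integer vector of protein atom_ids whose
# bipartite edges are removed (protein-graph edges are never masked).
# Returns the per-column probabilities plus (optionally) every intermediate
# needed for the backward pass.
forward_specnet <- function(params, input, config, mask = NULL,
                            keep_cache = FALSE) {
  d <- config$embed_dim
  A <- nrow(input$X)
  n <- input$n_pairs
  active <- config_active_groups(config)
  cache <- list(layers = list(), groups = list())

  H <- input$X %*% params$W_emb + rep(params$b_emb, each = A)
  cache$H0 <- H
  for (l in seq_len(config$n_protein_layers)) {
    lc <- list(H_in = H)
    if (length(input$src)) {
      Min <- cbind(H[input$src, , drop = FALSE], input$pe_rbf)
      Mpre <- Min %*% params[[paste0("W_msg", l)]] +
        rep(params[[paste0("b_msg", l)]], each = nrow(Min))
      M <- lrelu(Mpre)
      agg <- matrix(0, A, d)
      rs <- rowsum(M, group = input$dst)
      rows <- as.integer(rownames(rs))
      agg[rows, ] <- rs / pmax(input$deg[rows], 1L)
      lc$Min <- Min; lc$Mpre <- Mpre
    } else {
      agg <- matrix(0, A, d)
    }
    Uin <- cbind(H, agg)
    Upre <- Uin %*% params[[paste0("W_upd", l)]] +
      rep(params[[paste0("b_upd", l)]], each = A)
    U <- tanh(Upre)
    H <- H + U
    lc$Uin <- Uin; lc$U <- U
    cache$layers[[l]] <- lc
  }
  cache$H_final <- H

  Win <- config_flat_width(config)
  Z <- matrix(0, n, Win)
  for (gname in active) {
    g <- input$groups[[gname]]
    if (!g$n_pts) next
    keep <- if (is.null(mask) || !length(mask)) {
      seq_along(g$edge_atom)
    } else {
      which(!(input$atom_ids[g$edge_atom] %in% mask))
    }
    gm <- g
    if (length(keep) < length(g$edge_atom)) {
      gm$edge_atom <- g$edge_atom[keep]
      gm$edge_point <- g$edge_point[keep]
      gm$geo <- g$geo[keep, , drop = FALSE]
      em <- edge_index_matrix(gm$edge_point, g$n_pts)
      gm$IDX <- em$IDX; gm$cnt <- em$cnt
    }
    gc_ <- list(g = gm)
    if (length(gm$edge_atom)) {
      Bin <- cbind(H[gm$edge_atom, , drop = FALSE], gm$geo)
      Bpre <- Bin %*% params[[paste0("W_grp_", gname)]] +
        rep(params[[paste0("b_grp_", gname)]], each = nrow(Bin))
      B <- lrelu(Bpre)
      ag <- aggregate_mean_max(B, gm)
      gc_$Bin <- Bin; gc_$Bpre <- Bpre; gc_$AM <- ag$AM
      PV <- cbind(ag$PM, ag$PX)
    } else {
      PV <- matrix(0, gm$n_pts, 2 * d)
    }
    gc_$PV <- PV
    cache$groups[[gname]] <- gc_
    idx_rows <- rep(g$flat_row, times = 2 * d)
    idx_cols <- rep(g$flat_col0, times = 2 * d) +
      rep(seq_len(2 * d), each = g$n_pts)
    Z[cbind(idx_rows, idx_cols)] <- as.vector(PV)
  }
  extra0 <- 22L * d
  if (config_has_shape(config)) {
    Z[, extra0 + 1:4] <- input$shape
    extra0 <- extra0 + 4L
  }
  if (config_has_seq(config)) {
    Z[, extra0 + 1:4] <- input$seq
  }
  cache$Z <- Z

  k <- config$conv1d_kernel
  p <- (k - 1L) %/% 2L
  Cin <- Z
  cache$convs <- list()
  for (cl in seq_len(config$n_conv1d_layers)) {
    Zp <- rbind(matrix(0, p, ncol(Cin)), Cin, matrix(0, p, ncol(Cin)))
    U <- unfold1d(Zp, k, n)
    Cpre <- U %*% params[[paste0("W_conv", cl)]] +
      rep(params[[paste0("b_conv", cl)]], each = n)
    Cout <- lrelu(Cpre)
    cache$convs[[cl]] <- list(U = U, Cpre = Cpre, nin = ncol(Cin))
    Cin <- Cout
  }
  cache$C_last <- Cin
  logits <- Cin %*% params$W_head + rep(params$b_head, each = n)
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits)
  if (keep_cache) out$cache <- cache
  out
}

# Reverse-mode gradients for every parameter given dL/dlogits.
backward_specnet <- function(params, input, config, cache, dlogits) {
  d <- config$embed_dim
  A <- nrow(input$X)
  n <- input$n_pairs
  k <- config$conv1d_kernel
  p <- (k - 1L) %/% 2L
  grads <- list()

  grads$W_head <- t(cache$C_last) %*% dlogits
  grads$b_head <- colSums(dlogits)
  dC <- dlogits %*% t(params$W_head)

  for (cl in rev(seq_len(config$n_conv1d_layers))) {
    cv <- cache$convs[[cl]]
    dCpre <- dC * lrelu_grad(cv$Cpre)
    grads[[paste0("W_conv", cl)]] <- t(cv$U) %*% dCpre
    grads[[paste0("b_conv", cl)]] <- colSums(dCpre)
    dU <- dCpre %*% t(params[[paste0("W_conv", cl)]])
    nin <- cv$nin
    dZp <- matrix(0, n + 2 * p, nin)
    for (w in seq_len(k)) {
      dZp[w:(w + n - 1), ] <- dZp[w:(w + n - 1), ] +
        dU[, (w - 1L) * nin + seq_len(nin), drop = FALSE]
    }
    dC <- dZp[(p + 1):(p + n), , drop = FALSE]
  }
  dZ <- dC  # gradient w.r.t. the flattened pair features

  dH <- matrix(0, A, d)
  for (gname in names(cache$groups)) {
    gc_ <- cache$groups[[gname]]
    g <- gc_$g
    if (!g$n_pts) {
      grads[[paste0("W_grp_", gname)]] <- 0 * params[[paste0("W_grp_", gname)]]
      grads[[paste0("b_grp_", gname)]] <- 0 * params[[paste0("b_grp_", gname)]]
      next
    }
    idx_rows <- rep(g$flat_row, times = 2 * d)
    idx_cols <- rep(g$flat_col0, times = 2 * d) +
      rep(seq_len(2 * d), each = g$n_pts)
    dPV <- matrix(dZ[cbind(idx_rows, idx_cols)], g$n_pts, 2 * d)
    if (!length(g$edge_atom)) {
      grads[[paste0("W_grp_", gname)]] <- 0 * params[[paste0("W_grp_", gname)]]
      grads[[paste0("b_grp_", gname)]] <- 0 * params[[paste0("b_grp_", gname)]]
      next
    }
    dPM <- dPV[, seq_len(d), drop = FALSE]
    dPX <- dPV[, d + seq_len(d), drop = FALSE]
    m <- length(g$edge_atom)
    dB <- dPM[g$edge_point, , drop = FALSE] /
      pmax(g$cnt[g$edge_point], 1L)
    AM <- gc_$AM
    valid <- AM > 0L
    if (any(valid)) {
      ecol <- cbind(AM[valid], col(AM)[valid])
      dB[ecol] <- dB[ecol] + dPX[valid]
    }
    dBpre <- dB * lrelu_grad(gc_$Bpre)
    grads[[paste0("W_grp_", gname)]] <- t(gc_$Bin) %*% dBpre
    grads[[paste0("b_grp_", gname)]] <- colSums(dBpre)
    dBin <- dBpre %*% t(params[[paste0("W_grp_", gname)]])
    dHa <- dBin[, seq_len(d), drop = FALSE]
    rs <- rowsum(dHa, group = g$edge_atom)
    rows <- as.integer(rownames(rs))
    dH[rows, ] <- dH[rows, , drop = FALSE] + rs
  }
  for (gname in setdiff(GROUP_ORDER, names(cache$groups))) {
    grads[[paste0("W_grp_", gname)]] <- 0 * params[[paste0("W_grp_", gname)]]
    grads[[paste0("b_grp_", gname)]] <- 0 * params[[paste0("b_grp_", gname)]]
  }

  for (l in rev(seq_len(config$n_protein_layers))) {
    lc <- cache$layers[[l]]
    dU <- dH * (1 - lc$U^2)
    grads[[paste0("W_upd", l)]] <- t(lc$Uin) %*% dU
    grads[[paste0("b_upd", l)]] <- colSums(dU)
    dUin <- dU %*% t(params[[paste0("W_upd", l)]])
    dH_new <- dH + dUin[, seq_len(d), drop = FALSE]
    dagg <- dUin[, d + seq_len(d), drop = FALSE]
    if (!is.null(lc$Min)) {
      dM <- dagg[input$dst, , drop = FALSE] / pmax(input$deg[input$dst], 1L)
      dMpre <- dM * lrelu_grad(lc$Mpre)
      grads[[paste0("W_msg", l)]] <- t(lc$Min) %*% dMpre
      grads[[paste0("b_msg", l)]] <- colSums(dMpre)
      dMin <- dMpre %*% t(params[[paste0("W_msg", l)]])
      rs <- rowsum(dMin[, seq_len(d), drop = FALSE], group = input$src)
      rows <- as.integer(rownames(rs))
      dH_new[rows, ] <- dH_new[rows, , drop = FALSE] + rs
    } else {
      grads[[paste0("W_msg", l)]] <- 0 * params[[paste0("W_msg", l)]]
      grads[[paste0("b_msg", l)]] <- 0 * params[[paste0("b_msg", l)]]
    }
    dH <- dH_new
  }
  grads$W_emb <- t(input$X) %*% dH
  grads$b_emb <- colSums(dH)
  grads
}

# Adam optimizer state + step.
adam_init <- function(params) {
  list(m = lapply(params, function(p) 0 * p),
       v = lapply(params, function(p) 0 * p),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.01, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}
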