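# Edge-perturbation interpretation: relative importance (RI) of protein
# heavy atoms for the predicted specificity, with residue-level aggregates.
# Perturbation is exact per-forward-pass masking of an atom's bipartite
# edges, not gradient saliency.

predictor_for <- function(object) {
  if (inherits(object, "specnet_ensemble")) {
    list(config = object$config,
         fn = function(complex, mask, inputs) {
           members <- object$members
           mats <- lapply(members, function(m) {
             as_pwm_matrix(predict_pwm(m$model, complex, mask = mask,
                                       inputs = inputs)$pwm)
           })
           pwm(Reduce(`+`, mats) / length(mats))
         })
  } else {
    model <- if (inherits(object, "specnet")) object$model else object
    stopifnot(inherits(model, "specnet_model"))
    list(config = model$config,
         fn = function(complex, mask, inputs) {
           predict_pwm(model, complex, mask = mask, inputs = inputs)$pwm
         })
  }
}

#' Atoms within the bipartite cutoff of the sym-helix
#'
#' @param complex A `pdna_complex`.
#' @param r Cutoff in Angstrom.
#' @return Integer atom ids of protein heavy atoms within `r` of any present
#'   helix point.
#' @export
interface_atoms <- function(complex, r = 5.0) {
  helix <- build_sym_helix(complex)
  pts <- helix$points[helix$points$present, , drop = FALSE]
  P <- as.matrix(pts[, c("x", "y", "z")])
  X <- as.matrix(complex$protein_atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(X^2), rowSums(P^2), "+") - 2 * X %*% t(P)
  complex$protein_atoms$atom_id[apply(d2 <= r^2 + 1e-9, 1, any)]
}

#' Relative importance of protein heavy atoms
#'
#' For each atom a in scope the prediction is computed twice: unperturbed
#' (Y) and with atom a's bipartite edges masked (Y_~a). The raw effect is
#' `MAE(Y, Y_~a)`; relative importance is the raw effect divided by the
#' maximum raw effect within the structure, so RI lies in \[0, 1\] and the
#' most influential atom scores exactly 1. If no atom has any effect
#' (degenerate model) all RI are set to 0 with a warning. Residue-level
#' mean, max, sum and `log2(1 + sum)` aggregates are computed over each
#' residue's in-scope atoms.
#'
#' @param object A `specnet` fit, `specnet_ensemble` or `specnet_model`.
#' @param complex A `pdna_complex`.
#' @param scope Integer atom ids to perturb; defaults to all protein heavy
#'   atoms within the model's bipartite cutoff of the sym-helix.
#' @return Object of class `ri_result`: `per_atom` and `per_residue`
#'   data.frames, `reference_pwm`, `degenerate` flag.
#' @export
atom_importance <- function(object, complex, scope = NULL) {
  pr <- predictor_for(object)
  if (is.null(scope)) {
    scope <- interface_atoms(complex, r = pr$config$r_bipartite)
  }
  scope <- as.integer(scope)
  if (!length(scope)) stop("empty perturbation scope")
  inputs <- precompute_inputs(complex, pr$config)
  y0 <- pr$fn(complex, NULL, inputs)
  raw <- vapply(scope, function(a) {
    ya <- pr$fn(complex, edge_mask(a), inputs)
    pwm_mae(y0, ya)
  }, numeric(1))
  mx <- max(raw)
  degenerate <- mx <= 0
  if (degenerate) {
    warning("degenerate model: no atom perturbation changes the prediction")
    ri <- rep(0, length(raw))
  } else {
    ri <- raw / mx
  }
  pa <- complex$protein_atoms
  ix <- match(scope, pa$atom_id)
  res_key <- paste0(pa$chain_id[ix], ":", pa$residue_index[ix],
                    ifelse(nzchar(pa$insert[ix]), pa$insert[ix], ""))
  per_atom <- data.frame(
    atom_id = scope, chain = pa$chain_id[ix],
    residue_index = pa$residue_index[ix],
    residue_name = pa$residue_name[ix], atom_name = pa$atom_name[ix],
    residue = res_key, raw_mae = raw, ri = ri, stringsAsFactors = FALSE)
  agg <- lapply(split(per_atom, per_atom$residue), function(s) {
    data.frame(chain = s$chain[1], residue_index = s$residue_index[1],
               residue_name = s$residue_name[1], n_atoms = nrow(s),
               mean = mean(s$ri), max = max(s$ri), sum = sum(s$ri),
               logsum = log2(1 + sum(s$ri)), stringsAsFactors = FALSE)
  })
  per_residue <- do.call(rbind, agg)
  per_residue <- per_residue[order(per_residue$chain,
                                   per_residue$residue_index), ,
                             drop = FALSE]
  rownames(per_residue) <- NULL
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 reference_pwm = y0, degenerate = degenerate),
            class = "ri_result")
}

#' @export
print.ri_result <- function(x, ...) {
  cat("Relative importance over", nrow(x$per_atom), "interface atoms;",
      nrow(x$per_residue), "residues\n")
  top <- x$per_atom[order(-x$per_atom$ri), ][seq_len(min(5, nrow(x$per_atom))), ]
  print(top[, c("chain", "residue_index", "residue_name", "atom_name", "ri")],
        row.names = FALSE)
  invisible(x)
}

#' Write RI tables
#'
#' `<prefix>_atoms.tsv` (atom_id, chain, residue, atom_name, RI) and
#' `<prefix>_residues.tsv` (mean/max/sum/logsum aggregates).
#'
#' @param ri An `ri_result`.
#' @param prefix Output path prefix.
#' @export
write_ri_tables <- function(ri, prefix) {
  stopifnot(inherits(ri, "ri_result"))
  utils::write.table(ri$per_atom, paste0(prefix, "_atoms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ri$per_residue, paste0(prefix, "_residues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Write a PDB copy with RI stamped into B-factors
#'
#' Protein atoms in scope carry their RI (scaled to 0-99.99); everything
#' else gets 0. Intended for sphere-size visualization.
#'
#' @param ri An `ri_result`.
#' @param complex The complex the RI was computed on.
#' @param path Output PDB.
#' @export
stamp_ri_pdb <- function(ri, complex, path) {
  stopifnot(inherits(ri, "ri_result"), inherits(complex, "pdna_complex"))
  at <- rbind(complex$protein_atoms, complex$dna_atoms)
  b <- rep(0, nrow(at))
  m <- match(ri$per_atom$atom_id, at$atom_id)
  b[m[!is.na(m)]] <- round(ri$per_atom$ri[!is.na(m)] * 99.99, 2)
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$residue_index,
                   resid = at$residue_name, eleno = seq_len(nrow(at)),
                   elety = at$atom_name, chain = at$chain_id,
                   o = at$occupancy, b = b, elesy = at$element)
  invisible(path)
}
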