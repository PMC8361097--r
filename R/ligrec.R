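# Receptor-activity scoring and ligand-receptor interaction calling with a
# spatial co-expression filter.

#' Retain receptors with sufficiently large downstream signatures
#'
#' @param prior Ligand-receptor prior tibble (`ligand`, `receptor`,
#'   `signature` list-column); see [generate_lr_prior()].
#' @param min_genes Minimum signature size (default 5; a receptor with
#'   exactly 5 genes is retained).
#' @return List with `prior` (rows whose receptor passes) and `excluded`
#'   (tibble `receptor`, `n_signature_genes`).
#' @export
build_receptor_signatures <- function(prior, min_genes = 5L) {
  prior <- validate_lr_prior(prior)
  if (nrow(prior) == 0L) abort("empty ligand-receptor prior.")
  sizes <- prior |>
    dplyr::distinct(.data$receptor, .keep_all = TRUE) |>
    dplyr::transmute(.data$receptor,
                     n_signature_genes = lengths(.data$signature))
  bad <- sizes$receptor[sizes$n_signature_genes < min_genes]
  list(prior = dplyr::filter(prior, !.data$receptor %in% bad),
       excluded = dplyr::filter(sizes, .data$receptor %in% bad))
}

#' Per-cell receptor activity scores
#'
#' The activity of receptor `r` in cell `c` is the mean over the receptor's
#' signature genes of the absolute deviation of the cell's normalized
#' expression from the background mean of that gene, the background being
#' all cells sharing `c`'s broad compartment.
#'
#' @param expr Normalized cells x genes matrix.
#' @param broad Character vector of broad compartments, one per cell.
#' @param prior Prior with receptor signatures (pre-filtered through
#'   [build_receptor_signatures()]).
#' @return Cells x receptors numeric matrix of activities.
#' @export
receptor_activity <- function(expr, broad, prior) {
  assert_normalized(expr)
  if (length(broad) != nrow(expr)) abort("one broad label per cell required.")
  receptors <- dplyr::distinct(prior, .data$receptor, .keep_all = TRUE)
  act <- matrix(NA_real_, nrow(expr), nrow(receptors),
                dimnames = list(rownames(expr), receptors$receptor))
  for (bt in unique(broad)) {
    cells <- broad == bt
    mu_bg <- colMeans(expr[cells, , drop = FALSE])
    for (i in seq_len(nrow(receptors))) {
      genes <- intersect(receptors$signature[[i]], colnames(expr))
      if (!length(genes)) next
      dev <- abs(sweep(expr[cells, genes, drop = FALSE], 2L, mu_bg[genes], "-"))
      act[cells, i] <- rowMeans(dev)
    }
  }
  act
}

#' Call ligands available to each sender subtype
#'
#' A ligand is available to a subtype when its one-vs-all DE against cells
#' of the same broad compartment clears a minimum log2 fold change, a
#' maximum BH-adjusted p, and a minimum expressing fraction in the sender.
#'
#' @param de A `de_table` computed on ligand gene expression within a broad
#'   compartment (see [de_rank_genes()] with `scope`).
#' @param ligands Ligand genes under consideration.
#' @param min_lfc,max_padj,min_frac Thresholds (defaults 0.5, 0.05, 0.10);
#'   all boundaries are inclusive.
#' @return Tibble `subtype`, `ligand`.
#' @export
call_available_ligands <- function(de, ligands, min_lfc = 0.5,
                                   max_padj = 0.05, min_frac = 0.10) {
  de |>
    dplyr::filter(.data$gene %in% ligands,
                  .data$log2_fc >= min_lfc,
                  .data$p_adj <= max_padj,
                  .data$frac_expressing >= min_frac) |>
    dplyr::transmute(subtype = .data$group, ligand = .data$gene)
}

#' Call receptors active in each receiver subtype
#'
#' Receptor activities (from [receptor_activity()]) are tested for
#' enrichment in each subtype against the same broad compartment via the
#' same one-vs-all rank-sum machinery as gene DE; active receptors must
#' clear a log2 fold change of activity, an adjusted p, and a minimum
#' fraction of receiver cells expressing the receptor gene itself.
#'
#' @param activity Cells x receptors matrix.
#' @param expr Normalized cells x genes matrix (for receptor-gene
#'   expressing fractions).
#' @param subtypes,broad Subtype and compartment labels per cell.
#' @param scope_compartment Broad compartment whose subtypes are tested.
#' @param min_lfc,max_padj,min_frac Thresholds (defaults 0.25, 0.05, 0.10).
#' @return Tibble `subtype`, `receptor`.
#' @export
call_active_receptors <- function(activity, expr, subtypes, broad,
                                  scope_compartment, min_lfc = 0.25,
                                  max_padj = 0.05, min_frac = 0.10) {
  scope <- broad == scope_compartment
  act <- activity[scope, , drop = FALSE]
  act <- act[, colSums(is.na(act)) == 0L, drop = FALSE]
  attr(act, "normalized") <- TRUE  # activity is already on a linear scale
  de <- de_rank_genes(act, subtypes[scope], expm1_means = FALSE)
  frac <- de |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(rows, key) {
      in_g <- subtypes[scope] == key$group
      genes <- intersect(rows$gene, colnames(expr))
      f <- setNames(rep(0, nrow(rows)), rows$gene)
      f[genes] <- colMeans(expr[scope, genes, drop = FALSE][in_g, , drop = FALSE] > 0)
      rows$frac_receptor_expr <- unname(f[rows$gene])
      rows
    }) |>
    dplyr::ungroup()
  frac |>
    dplyr::filter(.data$log2_fc >= min_lfc,
                  .data$p_adj <= max_padj,
                  .data$frac_receptor_expr >= min_frac) |>
    dplyr::transmute(subtype = .data$group, receptor = .data$gene)
}

#' Spatial co-expression filter for candidate pairs
#'
#' A ligand-receptor pair passes when, in at least one spatial sample, at
#' least `min_frac` of the spots expressing the ligand (UMI > 0) also
#' express the receptor (UMI > 0). The boundary is inclusive. Pairs whose
#' genes are absent from every sample are dropped with a warning.
#'
#' @param spot_frames List of `spot_frame` objects (one per sample).
#' @param pairs Tibble with `ligand`, `receptor`.
#' @param min_frac Co-expression fraction threshold (default 0.25).
#' @return `pairs` with logical `spatially_coexpressed` and the best
#'   per-sample fraction `coexpression_frac`; rows failing gene lookup are
#'   removed.
#' @export
spatial_coexpression_filter <- function(spot_frames, pairs, min_frac = 0.25) {
  frac_one <- function(sf, ligand, receptor) {
    g <- colnames(sf$counts)
    if (!(ligand %in% g) || !(receptor %in% g)) return(NA_real_)
    lig_pos <- sf$counts[, ligand] > 0
    if (!any(lig_pos)) return(0)
    sum(sf$counts[lig_pos, receptor] > 0) / sum(lig_pos)
  }
  res <- purrr::pmap_dfr(pairs[, c("ligand", "receptor")], function(ligand, receptor) {
    f <- vapply(spot_frames, frac_one, numeric(1), ligand = ligand,
                receptor = receptor)
    tibble::tibble(ligand = ligand, receptor = receptor,
                   coexpression_frac = if (all(is.na(f))) NA_real_ else max(f, na.rm = TRUE))
  })
  absent <- is.na(res$coexpression_frac)
  if (any(absent)) {
    warn(sprintf("%d pairs dropped: genes absent from all spatial samples.",
                 sum(absent)))
  }
  res <- res[!absent, , drop = FALSE]
  res$spatially_coexpressed <- res$coexpression_frac >= min_frac
  res
}

#' Interaction potential of a sender-receiver pair
#'
#' @param ligand_expr Normalized ligand expression over sender-subtype cells.
#' @param receptor_activity Receptor activity over receiver-subtype cells.
#' @return Non-negative product of the two means.
#' @export
interaction_potential <- function(ligand_expr, receptor_activity) {
  mean(ligand_expr) * mean(receptor_activity)
}

#' Ribbon transparency for interaction rendering
#'
#' `min(0.9, 1 - (potential/potential_max)^2)`: the strongest interaction
#' rendered together with its peers is fully opaque and a 90% transparency
#' ceiling keeps the weakest ribbons visible.
#'
#' @param potential Non-negative interaction potential(s).
#' @param potential_max Maximum potential among records rendered together
#'   (positive).
#' @return Transparency value(s) in \[0, 0.9\].
#' @export
#' @examples
#' ribbon_transparency(c(0, 0.5, 1), potential_max = 1)
ribbon_transparency <- function(potential, potential_max) {
  if (potential_max <= 0) abort("`potential_max` must be positive.")
  if (any(potential < 0 | potential > potential_max)) {
    abort("`potential` must lie in [0, potential_max].")
  }
  pmin(0.9, 1 - (potential / potential_max)^2)
}

#' End-to-end ligand-receptor interaction analysis
#'
#' Runs the full calling pipeline for one sender subtype against receiver
#' subtypes of a receiver compartment: receptor-signature filtering, ligand
#' availability in the sender, receptor activity enrichment in receivers,
#' the spatial co-expression filter, and interaction potentials with ribbon
#' transparencies.
#'
#' @param expr Normalized cells x genes matrix.
#' @param cells Tibble with `cell_id`, `compartment`, `subtype` aligned to
#'   `expr` rows.
#' @param prior Ligand-receptor prior.
#' @param spot_frames List of `spot_frame`s for the spatial filter.
#' @param sender Sender subtype.
#' @param receiver_compartment Compartment whose subtypes receive.
#' @param min_sig_genes,ligand_min_lfc,receptor_min_lfc,max_padj,min_frac,
#'   spatial_min_frac Thresholds as in the stage functions.
#' @return Tibble (`interaction_set`): `sender`, `receiver`, `ligand`,
#'   `receptor`, `potential`, `transparency`, `coexpression_frac`.
#' @export
call_interactions <- function(expr, cells, prior, spot_frames, sender,
                              receiver_compartment, min_sig_genes = 5L,
                              ligand_min_lfc = 0.5, receptor_min_lfc = 0.25,
                              max_padj = 0.05, min_frac = 0.10,
                              spatial_min_frac = 0.25) {
  assert_normalized(expr)
  sigs <- build_receptor_signatures(prior, min_genes = min_sig_genes)
  prior <- sigs$prior
  sender_comp <- cells$compartment[match(sender, cells$subtype)]
  ligands <- intersect(unique(prior$ligand), colnames(expr))
  lig_expr <- expr[, ligands, drop = FALSE]
  attr(lig_expr, "normalized") <- TRUE
  de_send <- de_rank_genes(lig_expr, cells$subtype,
                           scope = cells$compartment == sender_comp)
  avail <- call_available_ligands(de_send, ligands,
                                  min_lfc = ligand_min_lfc,
                                  max_padj = max_padj, min_frac = min_frac) |>
    dplyr::filter(.data$subtype == sender)
  act <- receptor_activity(expr, cells$compartment, prior)
  active <- call_active_receptors(act, expr, cells$subtype, cells$compartment,
                                  receiver_compartment,
                                  min_lfc = receptor_min_lfc,
                                  max_padj = max_padj, min_frac = min_frac)
  cand <- prior |>
    dplyr::select("ligand", "receptor") |>
    dplyr::inner_join(avail, by = "ligand") |>
    dplyr::select(-"subtype") |>
    dplyr::inner_join(active, by = "receptor", relationship = "many-to-many") |>
    dplyr::rename(receiver = "subtype") |>
    dplyr::distinct()
  if (nrow(cand) == 0L) {
    out <- tibble::tibble(sender = character(0), receiver = character(0),
                          ligand = character(0), receptor = character(0),
                          potential = numeric(0), transparency = numeric(0),
                          coexpression_frac = numeric(0))
    class(out) <- c("interaction_set", class(out))
    return(out)
  }
  spatial <- spatial_coexpression_filter(
    spot_frames, dplyr::distinct(cand, .data$ligand, .data$receptor),
    min_frac = spatial_min_frac)
  cand <- cand |>
    dplyr::inner_join(spatial, by = c("ligand", "receptor")) |>
    dplyr::filter(.data$spatially_coexpressed)
  send_cells <- cells$subtype == sender
  out <- cand |>
    dplyr::mutate(sender = sender) |>
    dplyr::select("sender", "receiver", "ligand", "receptor",
                  "coexpression_frac")
  out$potential <- purrr::pmap_dbl(
    out[, c("ligand", "receptor", "receiver")],
    function(ligand, receptor, receiver) {
      interaction_potential(expr[send_cells, ligand],
                            act[cells$subtype == receiver, receptor])
    })
  pmax_val <- max(out$potential, 0)
  out$transparency <- if (pmax_val > 0) {
    ribbon_transparency(out$potential, pmax_val)
  } else rep(0.9, nrow(out))
  class(out) <- c("interaction_set", class(out))
  out
}
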