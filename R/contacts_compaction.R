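# Interface contact counting (8 A Calpha threshold), lateral-bond rupture
# tracking, and nucleotide compaction distances between ribose-ring
# centers of mass.

ca_indices <- function(structure, sel) {
  if (length(sel$atom_idx) == 0) return(integer(0))  # empty selection: 0 contacts
  idx <- sel$atom_idx[toupper(structure$atoms$elety[sel$atom_idx]) == "CA"]
  if (length(idx) == 0) stop("selection error: '", sel$label, "' has no Calpha atoms")
  idx
}

#' Count inter-selection Calpha contacts in one frame
#'
#' A contact is a residue pair (one residue from each selection) whose
#' Calpha-Calpha distance is strictly below the threshold.
#'
#' @param frame_xyz n x 3 coordinates of the frame.
#' @param structure the `structure_model` the selections refer to.
#' @param sel_a,sel_b disjoint `monomer_selection` objects.
#' @param threshold_A distance threshold, Angstrom (default 8; strict `<`).
#' @param method "cells" (spatial binning neighbor list, default) or
#'   "brute" (all-pairs double loop, the validation reference).
#' @return integer contact count.
#' @export
contact_count <- function(frame_xyz, structure, sel_a, sel_b,
                          threshold_A = 8, method = c("cells", "brute")) {
  method <- match.arg(method)
  if (length(intersect(sel_a$atom_idx, sel_b$atom_idx)))
    stop("selections overlap: contact counting needs disjoint selections")
  A <- frame_xyz[ca_indices(structure, sel_a), , drop = FALSE]
  B <- frame_xyz[ca_indices(structure, sel_b), , drop = FALSE]
  if (method == "brute") contact_count_brute(A, B, threshold_A)
  else contact_count_cells(A, B, threshold_A)
}

# all-pairs reference implementation
contact_count_brute <- function(A, B, threshold_A) {
  cnt <- 0L
  for (i in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
    cnt <- cnt + sum(d2 < threshold_A^2)
  }
  cnt
}

# cell-list implementation: bin B on a grid of cell edge = threshold, test
# each A point against its 27 neighbor cells only
contact_count_cells <- function(A, B, threshold_A) {
  if (nrow(A) == 0 || nrow(B) == 0) return(0L)
  h <- threshold_A
  origin <- pmin(apply(A, 2, min), apply(B, 2, min))
  keyB <- floor(sweep(B, 2, origin) / h)
  bins <- split(seq_len(nrow(B)), paste(keyB[, 1], keyB[, 2], keyB[, 3]))
  keyA <- floor(sweep(A, 2, origin) / h)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cnt <- 0L
  for (i in seq_len(nrow(A))) {
    for (o in seq_len(27)) {
      key <- paste(keyA[i, 1] + offs[o, 1], keyA[i, 2] + offs[o, 2],
                   keyA[i, 3] + offs[o, 3])
      jb <- bins[[key]]
      if (is.null(jb)) next
      d2 <- (B[jb, 1] - A[i, 1])^2 + (B[jb, 2] - A[i, 2])^2 + (B[jb, 3] - A[i, 3])^2
      cnt <- cnt + sum(d2 < h^2)
    }
  }
  cnt
}

#' Contact count time series along a trajectory
#'
#' Counts contacts at every sampled frame and flags lateral-bond rupture:
#' the first time the count reaches zero and stays zero for at least
#' `rupture_dwell` consecutive sampled frames.
#'
#' @param trajectory a `trajectory_ensemble`.
#' @param sel_a,sel_b disjoint `monomer_selection` objects.
#' @param threshold_A contact threshold, Angstrom (default 8).
#' @param stride keep every `stride`-th frame (default 1).
#' @param rupture_dwell frames the count must remain zero (default 10).
#' @return data.frame of class `contact_series` with `time_ns`, `count`;
#'   attributes `threshold_A` and `rupture_time_ns` (NA if no rupture).
#' @export
contact_series <- function(trajectory, sel_a, sel_b, threshold_A = 8,
                           stride = 1L, rupture_dwell = 10L) {
  idx <- seq(1, n_frames(trajectory), by = stride)
  counts <- vapply(idx, function(i) {
    contact_count(frame_coords(trajectory, i), trajectory$topology,
                  sel_a, sel_b, threshold_A)
  }, integer(1))
  rupture <- NA_real_
  zero <- counts == 0
  if (any(zero)) {
    run <- rle(zero)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1
    cand <- which(run$values & (run$lengths >= rupture_dwell |
                                  ends == length(zero)))
    hit <- cand[run$lengths[cand] >= rupture_dwell]
    if (length(hit)) rupture <- trajectory$times[idx][starts[hit[1]]]
  }
  out <- data.frame(time_ns = trajectory$times[idx], count = counts)
  class(out) <- c("contact_series", "data.frame")
  attr(out, "threshold_A") <- threshold_A
  attr(out, "rupture_time_ns") <- rupture
  out
}

#' Windowed contact summary across runs
#'
#' Mean and SD of the per-frame contact counts over the post-cutoff window
#' of each run, pooled across runs (the per-interface summary used for the
#' last-500-ns averages).
#'
#' @param series_list list of `contact_series` (one per run).
#' @param t_cut_ns window cutoff, ns (`NULL` = half of each run's span).
#' @return list with `mean`, `sd`, `n_frames`, `n_runs`.
#' @export
interface_contact_summary <- function(series_list, t_cut_ns = NULL) {
  if (is.data.frame(series_list)) series_list <- list(series_list)
  pooled <- unlist(lapply(series_list, function(s) {
    equilibrated_window(s, t_cut_ns)$count
  }), use.names = FALSE)
  list(mean = mean(pooled), sd = stats::sd(pooled),
       n_frames = length(pooled), n_runs = length(series_list))
}

#' Nucleotide compaction distance between two subunits
#'
#' Euclidean distance between the mass-weighted centers of the ribose-ring
#' atoms of the two nucleotides; the metric for longitudinal interface
#' compaction. By analysis convention only the minus-end-proximal
#' intra-dimer interface of a tetramer is reported.
#'
#' @param frame_xyz n x 3 frame coordinates.
#' @param structure the `structure_model` the selections refer to.
#' @param sel_a,sel_b `monomer_selection` objects with resolved
#'   nucleotides (`nuc_idx` non-empty).
#' @param ring_atoms ribose-ring atom names (default C1', C2', C3', C4',
#'   O4').
#' @return distance in Angstrom.
#' @export
compaction_distance <- function(frame_xyz, structure, sel_a, sel_b,
                                ring_atoms = .ribose_ring_atoms) {
  ring_com <- function(sel) {
    if (length(sel$nuc_idx) == 0)
      stop("selection '", sel$label, "' has no resolved nucleotide")
    nm <- toupper(gsub("\\*", "'", structure$atoms$elety[sel$nuc_idx]))
    hit <- sel$nuc_idx[nm %in% toupper(ring_atoms)]
    missing <- setdiff(toupper(ring_atoms), nm)
    if (length(missing))
      stop("nucleotide of '", sel$label, "' missing ribose-ring atoms: ",
           paste(missing, collapse = ", "))
    m <- atom_masses(structure)[hit]
    colSums(frame_xyz[hit, , drop = FALSE] * m) / sum(m)
  }
  vnorm(ring_com(sel_a) - ring_com(sel_b))
}

#' Compaction distance time series
#' @inheritParams compaction_distance
#' @param trajectory a `trajectory_ensemble`.
#' @param stride keep every `stride`-th frame.
#' @return data.frame with `time_ns`, `distance_A`.
#' @export
compaction_series <- function(trajectory, sel_a, sel_b,
                              ring_atoms = .ribose_ring_atoms, stride = 1L) {
  idx <- seq(1, n_frames(trajectory), by = stride)
  d <- vapply(idx, function(i) {
    compaction_distance(frame_coords(trajectory, i), trajectory$topology,
                        sel_a, sel_b, ring_atoms)
  }, numeric(1))
  data.frame(time_ns = trajectory$times[idx], distance_A = d)
}
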