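# Residue contact statistics: fractional occurrence with display/label
# tiers, overlap-coefficient (Szymkiewicz-Simpson) set comparisons, and
# agonist-vs-agonist profile contrasts.

#' Overlap coefficient between two residue sets
#'
#' `OC(A, B) = |A intersect B| / min(|A|, |B|)`. Equals 1 whenever one set
#' contains the other and 0 for disjoint sets. Chosen over Jaccard because
#' it does not penalize nested sets of unequal size.
#'
#' @param A,B vectors of residue ids (duplicates ignored); must be non-empty
#' @return numeric between 0 and 1
#' @export
overlap_coefficient <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0 || length(B) == 0)
    stop("overlap coefficient undefined for empty sets")
  length(intersect(A, B)) / min(length(A), length(B))
}

#' Per-cluster overlap-coefficient profile
#'
#' Computes the OC for every pathway pair within each cluster and compares
#' cluster means against the global mean over ALL pathway pairs (across
#' clusters). Clusters whose mean falls below the global mean carry the
#' signature of random, non-specific contacts.
#'
#' @param contact_sets list of residue-id vectors, one per pathway
#'   (typically `names(path$contact_residues)` of `lp_pathway`s)
#' @param labels cluster label per pathway (same length)
#' @return list with `global_mean`, `cluster` data.frame (`cluster`,
#'   `n_paths`, `n_pairs`, `mean_oc`, `below_global`), and `pair_oc`
#'   data.frame of all pairwise OCs
#' @export
cluster_oc_profile <- function(contact_sets, labels) {
  stopifnot(length(contact_sets) == length(labels))
  empty <- lengths(lapply(contact_sets, unique)) == 0
  if (any(empty)) {
    warning(sum(empty), " pathway(s) with empty contact sets excluded from OC")
    contact_sets <- contact_sets[!empty]
    labels <- labels[!empty]
  }
  n <- length(contact_sets)
  if (n < 2) stop("need at least two pathways with contacts")
  pairs <- utils::combn(n, 2)
  oc <- apply(pairs, 2, function(ij)
    overlap_coefficient(contact_sets[[ij[1]]], contact_sets[[ij[2]]]))
  pair_df <- data.frame(i = pairs[1, ] - 1L, j = pairs[2, ] - 1L,
                        cluster_i = labels[pairs[1, ]],
                        cluster_j = labels[pairs[2, ]], oc = oc)
  global_mean <- mean(oc)
  cl_ids <- sort(unique(labels))
  cl <- do.call(rbind, lapply(cl_ids, function(cid) {
    within <- pair_df$cluster_i == cid & pair_df$cluster_j == cid
    data.frame(cluster = cid, n_paths = sum(labels == cid),
               n_pairs = sum(within),
               mean_oc = if (any(within)) mean(pair_df$oc[within]) else NA_real_)
  }))
  cl$below_global <- !is.na(cl$mean_oc) & cl$mean_oc < global_mean
  list(global_mean = global_mean, cluster = cl, pair_oc = pair_df)
}

#' Build a contact profile from pathway contact data
#'
#' The primary statistic is pathway-level: a residue counts once per
#' pathway that contacts it anywhere along its trace. Frame-level counts
#' are also carried since display conventions differ.
#'
#' @param pathways list of `lp_pathway` objects (or list of residue-id
#'   vectors for pathway-level counting only)
#' @param scope label recorded on the profile (e.g. cluster id)
#' @return object of class `lp_contact_profile`: data.frame with
#'   `residue_id`, `pathway_count`, `frame_count`, `fraction`
#'   (pathway_count / max pathway_count), plus attributes `scope` and
#'   `basis = "pathway"`
#' @export
contact_profile <- function(pathways, scope = "all") {
  get_set <- function(p) if (inherits(p, "lp_pathway"))
    as.integer(names(p$contact_residues)) else as.integer(unique(p))
  get_frames <- function(p) if (inherits(p, "lp_pathway"))
    p$contact_residues else {
      counts <- rep(1L, length(unique(p))); names(counts) <- unique(p); counts
    }
  path_tab <- table(unlist(lapply(pathways, get_set)))
  frame_env <- new.env()
  for (p in pathways) {
    fc <- get_frames(p)
    for (r in names(fc)) {
      cur <- if (is.null(frame_env[[r]])) 0L else frame_env[[r]]
      frame_env[[r]] <- cur + fc[[r]]
    }
  }
  if (length(path_tab) == 0) stop("no residue contacts in any pathway")
  df <- data.frame(
    residue_id = as.integer(names(path_tab)),
    pathway_count = as.integer(path_tab)
  )
  df$frame_count <- vapply(as.character(df$residue_id),
                           function(r) as.integer(frame_env[[r]]), integer(1))
  df <- df[order(-df$pathway_count, df$residue_id), , drop = FALSE]
  rownames(df) <- NULL
  df$fraction <- df$pathway_count / max(df$pathway_count)
  structure(df, scope = scope, basis = "pathway",
            class = c("lp_contact_profile", "data.frame"))
}

#' Fractional-occurrence tiers of a contact profile
#'
#' Fractional occurrence is defined relative to the most contacted residue
#' in scope (the top residue is exactly 1). Residues at or above
#' `label_threshold` are labeled; those at or above `display_threshold`
#' are displayed; the rest are hidden.
#'
#' @param profile an `lp_contact_profile`, or a named count vector
#' @param label_threshold default 0.2
#' @param display_threshold default 0.1
#' @return data.frame `residue_id`, `fraction`, `tier` in
#'   {"labeled", "displayed", "hidden"}
#' @export
fractional_occurrence <- function(profile, label_threshold = 0.2,
                                  display_threshold = 0.1) {
  if (!inherits(profile, "lp_contact_profile")) {
    counts <- profile
    if (is.null(names(counts)) || length(counts) == 0)
      stop("need a contact profile or a named count vector")
    df <- data.frame(residue_id = names(counts),
                     fraction = as.numeric(counts) / max(as.numeric(counts)))
  } else {
    df <- data.frame(residue_id = profile$residue_id, fraction = profile$fraction)
  }
  df$tier <- ifelse(df$fraction >= label_threshold, "labeled",
                    ifelse(df$fraction >= display_threshold, "displayed", "hidden"))
  df[order(-df$fraction), , drop = FALSE]
}

#' Residues distinguishing two agonist profiles
#'
#' Flags residues whose fractional occurrence in profile X exceeds
#' `fold_threshold` times that in profile Y (and the converse). Residues
#' absent from one profile get `pseudo_fraction` there and are annotated.
#'
#' @param profile_x,profile_y `lp_contact_profile`s over the same subunit
#' @param fold_threshold default 10
#' @param pseudo_fraction fraction substituted for absent residues
#'   (default 0.01)
#' @return data.frame `residue_id`, `fraction_x`, `fraction_y`, `ratio`,
#'   `flagged_for` in {"x", "y", ""}, `absent_in_other`
#' @export
compare_agonists <- function(profile_x, profile_y, fold_threshold = 10,
                             pseudo_fraction = 0.01) {
  fx <- stats::setNames(profile_x$fraction, profile_x$residue_id)
  fy <- stats::setNames(profile_y$fraction, profile_y$residue_id)
  all_res <- sort(unique(as.integer(c(names(fx), names(fy)))))
  key <- as.character(all_res)
  x <- fx[key]; y <- fy[key]
  absent <- is.na(x) | is.na(y)
  x[is.na(x)] <- pseudo_fraction
  y[is.na(y)] <- pseudo_fraction
  ratio <- x / y
  flagged <- ifelse(ratio > fold_threshold, "x",
                    ifelse(1 / ratio > fold_threshold, "y", ""))
  data.frame(residue_id = all_res, fraction_x = unname(x),
             fraction_y = unname(y), ratio = unname(ratio),
             flagged_for = unname(flagged), absent_in_other = unname(absent))
}
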