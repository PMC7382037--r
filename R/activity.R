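# Metatranscriptome-based activity thresholds (% of mapped reads).
ACTIVE_THRESHOLD_BACTERIA <- 0.4
ACTIVE_THRESHOLD_ARCHAEA <- 0.3
# Minimum activity fraction for a reactor to qualify for the
# expression-consistency (ECM50) rule, and the required consistency.
ECM_QUALIFY_FRACTION <- 0.05
ECM_CONSISTENCY <- 0.5

#' Normalize a MAG's expression profile
#'
#' Divides each gene's RPKM by the median RPKM of the MAG's coding genes.
#' By default the median is taken over non-zero values (a MAG's silent
#' genes do not deflate the reference level); set `nonzero_median = FALSE`
#' to use the plain median. A MAG with no expressed gene yields all-NA
#' values with a warning.
#'
#' @param rpkm Named numeric vector of RPKM values for one MAG in one
#'   sample (gene_id -> RPKM). Genes of the MAG missing from the profile
#'   are treated as 0 (with a warning) when `genes` is supplied.
#' @param genes Optional character vector of the MAG's gene ids.
#' @param nonzero_median Use the non-zero median as reference (default).
#' @return Named numeric vector of normalized expression levels.
#' @export
#' @examples
#' normalize_expression(c(g1 = 2, g2 = 4, g3 = 8))
normalize_expression <- function(rpkm, genes = NULL, nonzero_median = TRUE) {
  stopifnot(is.numeric(rpkm), !is.null(names(rpkm)))
  if (any(rpkm < 0)) stop("RPKM values must be non-negative")
  if (!is.null(genes)) {
    missing <- setdiff(genes, names(rpkm))
    if (length(missing) > 0) {
      warning(length(missing), " gene(s) missing from profile; treated as 0")
      rpkm[missing] <- 0
    }
    rpkm <- rpkm[genes]
  }
  ref_vals <- if (nonzero_median) rpkm[rpkm > 0] else rpkm
  if (length(ref_vals) == 0 || stats::median(ref_vals) == 0) {
    warning("MAG has no expressed genes; normalized levels undefined")
    return(stats::setNames(rep(NA_real_, length(rpkm)), names(rpkm)))
  }
  rpkm / stats::median(ref_vals)
}

#' Assemble an expression profile set
#'
#' @param table data.frame with columns `reactor_id`, `replicate_id`,
#'   `gene_id`, `rpkm`.
#' @return Object of class `expression_set` (the validated table).
#' @export
expression_set <- function(table) {
  stopifnot(all(c("reactor_id", "replicate_id", "gene_id", "rpkm")
                %in% names(table)))
  if (any(table$rpkm < 0)) stop("RPKM values must be non-negative")
  reps <- tapply(table$replicate_id, table$reactor_id,
                 function(x) length(unique(x)))
  if (any(reps != 3)) {
    message("note: reactors without triplicate profiles: ",
            paste(names(reps)[reps != 3], collapse = ", "))
  }
  structure(table, class = c("expression_set", "data.frame"))
}

# Replicate-averaged normalized expression per gene for one reactor.
# Normalization is per replicate (each replicate has its own median),
# then the arithmetic mean over replicates is taken.
reactor_normalized_means <- function(exprs, reactor, genes,
                                     nonzero_median = TRUE) {
  sub <- exprs[exprs$reactor_id == reactor, , drop = FALSE]
  if (nrow(sub) == 0) return(stats::setNames(rep(NA_real_, length(genes)), genes))
  reps <- split(sub, sub$replicate_id)
  mat <- vapply(reps, function(r) {
    v <- stats::setNames(r$rpkm, r$gene_id)
    suppressWarnings(normalize_expression(v, genes = genes,
                                          nonzero_median = nonzero_median))
  }, numeric(length(genes)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(genes))
  rowMeans(mat, na.rm = FALSE)
}

#' Pathway activity call for one genome in one reactor
#'
#' A pathway is called active when, for every enzyme step, the
#' best-matching gene's replicate-averaged normalized expression level is
#' >= `level_min` (default 1).
#'
#' @param genome A [genome_annotation()].
#' @param pathway A `pathway_def`.
#' @param exprs An [expression_set()] restricted to one MAG's genes.
#' @param reactor Reactor id.
#' @param level_min Expression threshold on the normalized level.
#' @param nonzero_median Passed to [normalize_expression()].
#' @return List with `active` (flag) and `step_levels` (best level per step).
#' @export
pathway_active <- function(genome, pathway, exprs, reactor, level_min = 1,
                           nonzero_median = TRUE) {
  genes <- genome$genes$gene_id
  levels <- reactor_normalized_means(exprs, reactor, genes, nonzero_median)
  step_levels <- vapply(pathway$steps, function(step) {
    ids <- unique(unlist(lapply(step, genes_with_label, genome = genome)))
    vals <- levels[ids]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NA_real_)
    max(vals)
  }, numeric(1))
  list(active = all(!is.na(step_levels)) && all(step_levels >= level_min),
       step_levels = step_levels)
}

#' Transcriptome activity fractions of species clusters
#'
#' Percentage of mapped transcriptome reads assigned to each cluster in
#' each reactor. Two denominators are reported: all mapped reads
#' (`pct_all`) and, after a first activity call on the all-reads
#' denominator, reads mapped to active species only (`pct_active`).
#'
#' @param read_counts data.frame with columns `cluster_id`, `reactor_id`,
#'   `reads` (summed over replicates).
#' @param domain Named character vector: cluster_id -> "bacteria" or
#'   "archaea" (for the activity thresholds).
#' @param thresholds Length-2 numeric: activity thresholds (%) for
#'   bacteria and archaea.
#' @return data.frame with columns `cluster_id`, `reactor_id`, `pct_all`,
#'   `pct_active` (NA for clusters outside the active set), plus a
#'   per-cluster `active` flag merged on.
#' @export
activity_fraction <- function(read_counts, domain,
                              thresholds = c(bacteria = ACTIVE_THRESHOLD_BACTERIA,
                                             archaea = ACTIVE_THRESHOLD_ARCHAEA)) {
  stopifnot(all(c("cluster_id", "reactor_id", "reads") %in% names(read_counts)))
  rc <- read_counts
  tot <- tapply(rc$reads, rc$reactor_id, sum)
  rc$pct_all <- 100 * rc$reads / as.numeric(tot[as.character(rc$reactor_id)])
  # first pass: active on the all-reads denominator
  act <- call_active(rc, domain, pct_col = "pct_all", thresholds = thresholds)
  rc$active <- act[rc$cluster_id]
  tot_act <- tapply(rc$reads[rc$active], rc$reactor_id[rc$active], sum)
  rc$pct_active <- ifelse(
    rc$active,
    100 * rc$reads / as.numeric(tot_act[as.character(rc$reactor_id)]),
    NA_real_)
  rc
}

#' Call active species clusters
#'
#' A cluster is active when its transcriptome fraction reaches the
#' domain-specific threshold (>= 0.4% for bacteria, >= 0.3% for archaea)
#' in at least one reactor.
#'
#' @param fractions data.frame with `cluster_id`, `reactor_id` and a
#'   percentage column.
#' @param domain Named character vector: cluster_id -> domain.
#' @param pct_col Name of the percentage column (default `pct_all`).
#' @param thresholds Named numeric thresholds per domain.
#' @return Named logical vector per cluster.
#' @export
call_active <- function(fractions, domain, pct_col = "pct_all",
                        thresholds = c(bacteria = ACTIVE_THRESHOLD_BACTERIA,
                                       archaea = ACTIVE_THRESHOLD_ARCHAEA)) {
  cl <- unique(fractions$cluster_id)
  unknown <- setdiff(cl, names(domain))
  if (length(unknown) > 0) {
    stop("no domain given for cluster(s): ", paste(unknown, collapse = ", "))
  }
  out <- vapply(cl, function(ci) {
    thr <- thresholds[[domain[[ci]]]]
    any(fractions[fractions$cluster_id == ci, pct_col] >= thr)
  }, logical(1))
  names(out) <- cl
  out
}

#' Expression-consistency (ECM50) call
#'
#' A cluster consistently expresses a pathway when the pathway is active
#' in at least 50% of the qualifying reactors -- those where the cluster
#' comprises >= 0.05% of the mapped metatranscriptome. With no qualifying
#' reactor the call is undefined (NA), not FALSE.
#'
#' @param active_by_reactor Named logical vector: reactor_id -> pathway
#'   active in that reactor.
#' @param fraction_by_reactor Named numeric vector: reactor_id -> the
#'   cluster's transcriptome percentage there.
#' @param qualify_pct Qualifying threshold (%); default 0.05.
#' @param consistency Required fraction of qualifying reactors; default 0.5.
#' @return TRUE/FALSE, or NA when undefined.
#' @export
#' @examples
#' ecm50(c(r1 = TRUE, r2 = FALSE, r3 = TRUE, r4 = FALSE),
#'       c(r1 = 1, r2 = 0.2, r3 = 0.06, r4 = 0.01))
ecm50 <- function(active_by_reactor, fraction_by_reactor,
                  qualify_pct = ECM_QUALIFY_FRACTION,
                  consistency = ECM_CONSISTENCY) {
  common <- intersect(names(active_by_reactor), names(fraction_by_reactor))
  qual <- common[fraction_by_reactor[common] >= qualify_pct]
  if (length(qual) == 0) return(NA)
  mean(active_by_reactor[qual]) >= consistency
}

#' Assemble the cluster-level activity matrix
#'
#' For each species cluster: per-reactor activity fractions, the active
#' flag, per-(reactor, pathway) activity calls for its capacities, and the
#' ECM50 consistency flag per pathway.
#'
#' @param genomes List of [genome_annotation()] objects.
#' @param capacities `per_mag` capacity calls from [capacity_matrix()]
#'   (pathways with `capacity` or `ambiguous` are evaluated for activity).
#' @param exprs An [expression_set()] covering all genes.
#' @param read_counts Cluster x reactor read counts (see
#'   [activity_fraction()]).
#' @param domain Named domain vector per cluster.
#' @param catalog Pathway catalog.
#' @param level_min Normalized-expression threshold (default 1).
#' @return List with `fractions` (per cluster x reactor), `active`
#'   (per cluster), `pathway_activity` (long data.frame: cluster, pathway,
#'   reactor, active) and `ecm50` (cluster x pathway calls).
#' @export
activity_matrix <- function(genomes, capacities, exprs, read_counts, domain,
                            catalog = pathway_catalog(), level_min = 1) {
  fr <- activity_fraction(read_counts, domain)
  act <- call_active(fr, domain)
  mag_cluster <- stats::setNames(vapply(genomes, `[[`, "", "cluster_id"),
                                 vapply(genomes, `[[`, "", "mag_id"))
  reactors <- sort(unique(fr$reactor_id))
  eligible <- capacities[capacities$capacity |
                           (capacities$ambiguous & capacities$complete &
                              !is.na(capacities$balanced) &
                              capacities$balanced), , drop = FALSE]
  rows <- list()
  ecm_rows <- list()
  for (cl in sort(unique(eligible$cluster_id))) {
    cl_caps <- unique(eligible$pathway[eligible$cluster_id == cl])
    members <- genomes[mag_cluster[vapply(genomes, `[[`, "", "mag_id")] == cl]
    cl_frac <- stats::setNames(
      fr$pct_all[fr$cluster_id == cl][match(reactors,
                                            fr$reactor_id[fr$cluster_id == cl])],
      reactors)
    for (pw in cl_caps) {
      by_reactor <- vapply(reactors, function(rx) {
        any(vapply(members, function(g) {
          sub <- exprs[exprs$gene_id %in% g$genes$gene_id, , drop = FALSE]
          pathway_active(g, catalog[[pw]], sub, rx, level_min)$active
        }, logical(1)))
      }, logical(1))
      names(by_reactor) <- reactors
      rows[[length(rows) + 1]] <-
        data.frame(cluster_id = cl, pathway = pw, reactor_id = reactors,
                   active = unname(by_reactor), stringsAsFactors = FALSE)
      ecm_rows[[length(ecm_rows) + 1]] <-
        data.frame(cluster_id = cl, pathway = pw,
                   ecm50 = ecm50(by_reactor, cl_frac),
                   stringsAsFactors = FALSE)
    }
  }
  list(fractions = fr, active = act,
       pathway_activity = do.call(rbind, rows),
       ecm50 = do.call(rbind, ecm_rows))
}
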