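# Aromatic residues counted by the conductive-pilin rule.
AROMATIC_RESIDUES <- c("F", "W", "Y", "H")
# Window length (aa) over which aromatics must be distributed.
PILIN_WINDOW <- 20
# Minimum aromatic fraction of the peptide.
PILIN_AROMATIC_FRACTION <- 0.09
# Heme-binding motifs required for a multiheme cytochrome call.
HEME_MIN <- 2
# Maximum intergenic gap (bp) within an operon.
OPERON_GAP_MAX <- 500

#' Assemble a genome annotation object
#'
#' Per-MAG gene records: ortholog/function labels (semicolon-separated in
#' files, a character vector per gene here), contig, 1-based inclusive
#' coordinates, strand, and optional protein sequences.
#'
#' @param mag_id MAG identifier.
#' @param genes data.frame with columns `gene_id`, `labels` (list column or
#'   semicolon-separated character), `contig`, `start`, `end`, `strand`.
#' @param cluster_id Species-cluster identifier (optional).
#' @param proteins Named character vector of protein sequences keyed by
#'   `gene_id` (optional).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(mag_id, genes, cluster_id = NA_character_,
                              proteins = character(0)) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "labels", "contig", "start", "end", "strand")
                %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique within a MAG")
  genes$labels <- if (is.list(genes$labels)) {
    lapply(unclass(genes$labels), as.character)
  } else {
    strsplit(as.character(genes$labels), ";", fixed = TRUE)
  }
  if (any(genes$start < 1 | genes$end < genes$start)) {
    stop("coordinates must be 1-based inclusive with end >= start")
  }
  structure(list(mag_id = mag_id, cluster_id = cluster_id, genes = genes,
                 proteins = proteins),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome> %s (cluster %s): %d genes on %d contig(s)\n",
              x$mag_id, x$cluster_id, nrow(x$genes),
              length(unique(x$genes$contig))))
  invisible(x)
}

# All labels annotated on a genome (flat character vector).
genome_labels <- function(genome) unique(unlist(genome$genes$labels))

# gene_ids carrying a given label.
genes_with_label <- function(genome, label) {
  hit <- vapply(genome$genes$labels, function(l) label %in% l, logical(1))
  genome$genes$gene_id[hit]
}

#' Test pathway completeness in a genome
#'
#' A pathway is complete when every enzyme step has at least one gene
#' carrying one of the step's alternative ortholog labels.
#'
#' @param genome A [genome_annotation()].
#' @param pathway A `pathway_def` from [pathway_catalog()].
#' @return List with `complete` (flag), `witness` (per-step matched gene
#'   ids) and `missing_steps` (indices of unmatched steps).
#' @export
pathway_complete <- function(genome, pathway) {
  witness <- lapply(pathway$steps, function(step) {
    unique(unlist(lapply(step, genes_with_label, genome = genome)))
  })
  names(witness) <- vapply(pathway$steps, paste, "", collapse = "|")
  missing <- which(vapply(witness, length, 0L) == 0)
  list(complete = length(missing) == 0, witness = witness,
       missing_steps = unname(missing))
}

#' Test presence of a co-localised multi-subunit complex
#'
#' A complex is credited when all subunits occur on one contig, on the same
#' strand, consecutively with intergenic gaps <= `gap_max` -- or when the
#' operon is split across exactly two contig ends (each partial run
#' terminating at a contig boundary, i.e. first or last annotated gene of
#' its contig).
#'
#' @param genome A [genome_annotation()].
#' @param subunits Character vector of subunit ortholog labels (>= 2).
#' @param gap_max Maximum intergenic gap in bp (default 500).
#' @param require_strand Require all subunits on one strand (default TRUE).
#' @return TRUE/FALSE.
#' @export
complex_present <- function(genome, subunits, gap_max = OPERON_GAP_MAX,
                            require_strand = TRUE) {
  stopifnot(length(subunits) >= 2)
  g <- genome$genes
  sub_of <- lapply(g$labels, function(l) intersect(subunits, l))
  idx <- which(vapply(sub_of, length, 0L) > 0)
  if (length(idx) == 0) return(FALSE)
  hits <- g[idx, , drop = FALSE]
  hits$subunit <- vapply(sub_of[idx], `[[`, "", 1)
  if (!all(subunits %in% hits$subunit)) return(FALSE)

  # candidate runs: per contig (and strand), genes sorted by start,
  # split where the intergenic gap exceeds gap_max or a non-subunit
  # annotated gene intervenes
  runs <- list()
  for (ctg in unique(hits$contig)) {
    all_ctg <- g[g$contig == ctg, , drop = FALSE]
    all_ctg <- all_ctg[order(all_ctg$start), , drop = FALSE]
    is_hit <- all_ctg$gene_id %in% hits$gene_id
    run_start <- NULL
    for (i in seq_len(nrow(all_ctg) + 1)) {
      ok <- i <= nrow(all_ctg) && is_hit[i] &&
        (is.null(run_start) ||
           (all_ctg$start[i] - all_ctg$end[i - 1] - 1 <= gap_max &&
              (!require_strand ||
                 all_ctg$strand[i] == all_ctg$strand[run_start])))
      if (ok) {
        if (is.null(run_start)) run_start <- i
      } else {
        if (!is.null(run_start)) {
          runs[[length(runs) + 1]] <-
            list(contig = ctg,
                 genes = all_ctg$gene_id[run_start:(i - 1)],
                 at_start = run_start == 1,
                 at_end = (i - 1) == nrow(all_ctg))
          run_start <- if (i <= nrow(all_ctg) && is_hit[i]) i else NULL
        }
      }
    }
  }
  run_subunits <- lapply(runs, function(r) {
    unique(hits$subunit[hits$gene_id %in% r$genes])
  })
  # single-operon case
  if (any(vapply(run_subunits, function(s) all(subunits %in% s), logical(1)))) {
    return(TRUE)
  }
  # split across two contig ends
  if (length(runs) >= 2) {
    pairs <- utils::combn(length(runs), 2, simplify = FALSE)
    for (p in pairs) {
      r1 <- runs[[p[1]]]; r2 <- runs[[p[2]]]
      if (r1$contig == r2$contig) next
      boundary1 <- r1$at_start || r1$at_end
      boundary2 <- r2$at_start || r2$at_end
      if (boundary1 && boundary2 &&
          all(subunits %in% union(run_subunits[[p[1]]], run_subunits[[p[2]]]))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Conductive-pilin sequence rule
#'
#' A pilin is called conductive when aromatic residues (F, W, Y, H) make up
#' at least 9% of the peptide and are distributed across its whole length:
#' every disjoint 20-residue window (the last window may be shorter)
#' contains at least one aromatic residue. Case-insensitive.
#'
#' @param protein Amino-acid sequence (single string, length >= 20).
#' @return TRUE/FALSE.
#' @export
#' @examples
#' conductive_pili(make_pilin(100, 0.10, clustered = FALSE))
conductive_pili <- function(protein) {
  protein <- toupper(as.character(protein))
  if (nchar(protein) == 0) stop("empty protein sequence")
  if (nchar(protein) < PILIN_WINDOW) {
    stop("sequence shorter than one ", PILIN_WINDOW, "-residue window")
  }
  aa <- strsplit(protein, "")[[1]]
  arom <- aa %in% AROMATIC_RESIDUES
  if (mean(arom) < PILIN_AROMATIC_FRACTION) return(FALSE)
  windows <- split(arom, ceiling(seq_along(arom) / PILIN_WINDOW))
  all(vapply(windows, any, logical(1)))
}

#' Multiheme-cytochrome sequence rule
#'
#' Called for proteins with at least `heme_min` CXXCH heme-binding motifs
#' (overlap-aware, case-insensitive) that are membrane-bound or
#' extracellular. Localization is input metadata (signal-peptide and
#' transmembrane prediction are upstream of this package).
#'
#' @param protein Amino-acid sequence.
#' @param localization One of `"extracellular"`, `"membrane"`, `"other"`.
#' @param heme_min Minimum number of CXXCH motifs (default 2).
#' @return TRUE/FALSE.
#' @export
multiheme_cytochrome <- function(protein, localization, heme_min = HEME_MIN) {
  localization <- match.arg(localization, c("extracellular", "membrane", "other"))
  protein <- toupper(as.character(protein))
  n_motif <- length(gregexpr("(?=C..CH)", protein, perl = TRUE)[[1]])
  if (n_motif == 1 && gregexpr("(?=C..CH)", protein, perl = TRUE)[[1]][1] == -1) {
    n_motif <- 0
  }
  n_motif >= heme_min && localization %in% c("extracellular", "membrane")
}

#' Electron-carrier re-oxidation balance
#'
#' Builds the directed carrier graph for a genome -- carrier nodes (NADH,
#' NADPH, FdH2, ETFH2, quinol), sink nodes (H2 via encoded hydrogenases,
#' formate via formate dehydrogenases, O2 via bd oxidase, extracellular
#' transfer via validated multiheme cytochromes), with edges contributed by
#' the co-localised complexes and single-gene transfer enzymes the genome
#' encodes -- and checks that every carrier the pathway generates can reach
#' at least one sink. Pathways with no external carriers pass vacuously.
#'
#' @param genome A [genome_annotation()].
#' @param pathway A `pathway_def`.
#' @param defs Electron-transfer definitions ([electron_transfer_defs()]).
#' @param localizations Named character vector of protein localizations
#'   (for the multiheme-cytochrome sequence rule), keyed by gene_id.
#' @return List with `balanced` (flag), `routing` (per-carrier reachable
#'   sinks), `graph` (the igraph object) and `present` (enzymes credited).
#' @export
electron_balance <- function(genome, pathway, defs = electron_transfer_defs(),
                             localizations = character(0)) {
  edges <- character(0)
  present <- character(0)
  for (nm in names(defs$complexes)) {
    cx <- defs$complexes[[nm]]
    if (complex_present(genome, unlist(cx$subunits))) {
      present <- c(present, nm)
      for (e in cx$edges) edges <- c(edges, e[[1]], e[[2]])
    }
  }
  for (nm in names(defs$singles)) {
    sg <- defs$singles[[nm]]
    gene_ids <- genes_with_label(genome, sg$gene)
    if (length(gene_ids) == 0) next
    ok <- TRUE
    if (identical(sg$sequence_rule, "multiheme_cytochrome")) {
      ok <- any(vapply(gene_ids, function(gid) {
        seq <- genome$proteins[gid]
        loc <- if (gid %in% names(localizations)) localizations[[gid]] else "other"
        !is.na(seq) && multiheme_cytochrome(seq, loc)
      }, logical(1)))
    }
    if (ok) {
      present <- c(present, nm)
      for (e in sg$edges) edges <- c(edges, e[[1]], e[[2]])
    }
  }
  nodes <- unique(c(defs$carriers, defs$sinks, edges))
  gr <- igraph::make_empty_graph(n = 0, directed = TRUE)
  gr <- igraph::add_vertices(gr, length(nodes), name = nodes)
  if (length(edges) > 0) gr <- igraph::add_edges(gr, match(edges, nodes))
  carriers <- pathway$carriers_generated
  routing <- list()
  balanced <- TRUE
  for (ca in carriers) {
    reach <- names(igraph::subcomponent(gr, ca, mode = "out"))
    sinks <- intersect(reach, defs$sinks)
    routing[[ca]] <- sinks
    if (length(sinks) == 0) balanced <- FALSE
  }
  list(balanced = balanced, routing = routing, graph = gr, present = present)
}

#' Predict a metabolic capacity for one genome and pathway
#'
#' Applies the four reconstruction criteria: (i) the pathway is complete,
#' (ii) every generated electron carrier can be re-oxidised to a sink,
#' (iii) the ledger yields net positive energy conservation, and (iv) the
#' pathway is exergonic in situ under the supplied conditions. Pathways
#' whose directionality cannot be resolved from sequence alone are emitted
#' with an `ambiguous` flag and not asserted as capacities.
#'
#' @param genome A [genome_annotation()].
#' @param pathway A `pathway_def`.
#' @param cond A [conditions()]. If no H2 partial pressure is set, the
#'   exergonicity check uses the pathway-permissive convention: in-situ H2
#'   spans roughly 0.1 Pa (methyl-reducing methanogen partners) to 10 Pa
#'   (bulk digester levels), so H2-producing pathways are checked at the
#'   low end (0.1 Pa) and H2-consuming ones at the high end (10 Pa).
#' @param defs Electron-transfer definitions.
#' @param constants Constants table.
#' @param localizations Optional localization metadata (see
#'   [electron_balance()]).
#' @return One-row data.frame: mag_id, pathway, complete, balanced,
#'   atp_yield, delta_g, capacity (flag), ambiguous, reason.
#' @export
capacity_predict <- function(genome, pathway,
                             cond = digester_conditions(),
                             defs = electron_transfer_defs(),
                             constants = formation_energies(),
                             localizations = character(0)) {
  comp <- pathway_complete(genome, pathway)
  atp <- atp_yield(pathway$ledger)
  bal <- if (comp$complete) {
    electron_balance(genome, pathway, defs, localizations)$balanced
  } else NA
  needs_h2 <- "h2" %in% names(pathway$reaction$stoich)
  if (needs_h2 && !("h2" %in% names(cond$activities))) {
    cond$activities["h2"] <-
      if (pathway$reaction$stoich[["h2"]] > 0) 0.1 else 10
  }
  dg <- tryCatch(net_delta_g(pathway$reaction, cond, atp, constants),
                 error = function(e) NA_real_)
  ambiguous <- identical(pathway$directionality, "ambiguous")
  reason <- NULL
  if (!comp$complete) reason <- c(reason, "incomplete")
  if (isFALSE(bal)) reason <- c(reason, "carrier not re-oxidized")
  if (atp <= 0) reason <- c(reason, "no net energy conservation")
  if (!is.na(dg) && dg >= 0) reason <- c(reason, "not exergonic")
  if (ambiguous) reason <- c(reason, "ambiguous directionality")
  capacity <- comp$complete && isTRUE(bal) && atp > 0 &&
    (!is.na(dg) && dg < 0) && !ambiguous
  data.frame(mag_id = genome$mag_id, pathway = pathway$id,
             complete = comp$complete, balanced = bal, atp_yield = atp,
             delta_g = dg, capacity = capacity, ambiguous = ambiguous,
             reason = if (is.null(reason)) "" else paste(reason, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Cluster MAGs into species by pairwise distance
#'
#' Single-linkage components of the graph whose edges connect MAG pairs
#' with pairwise mutation distance <= `cutoff` (default 0.05, i.e. >= 95%
#' average nucleotide identity). Cluster labels are deterministic: each
#' cluster is named after its lexicographically smallest member.
#'
#' @param distances data.frame with columns `mag1`, `mag2`, `distance`, or
#'   a symmetric distance matrix with MAG ids as dimnames.
#' @param cutoff Distance cutoff (default 0.05).
#' @return Named character vector: MAG id -> cluster label.
#' @export
#' @examples
#' d <- data.frame(mag1 = c("a", "b"), mag2 = c("b", "c"),
#'                 distance = c(0.04, 0.2))
#' cluster_species(d)
cluster_species <- function(distances, cutoff = 0.05) {
  if (is.matrix(distances)) {
    mags <- rownames(distances)
    stopifnot(!is.null(mags), isTRUE(all.equal(distances, t(distances))))
    idx <- which(upper.tri(distances), arr.ind = TRUE)
    distances <- data.frame(mag1 = mags[idx[, 1]], mag2 = mags[idx[, 2]],
                            distance = distances[idx])
  }
  stopifnot(all(c("mag1", "mag2", "distance") %in% names(distances)))
  if (any(distances$distance < 0 | distances$distance > 1)) {
    stop("distances must lie in [0, 1]")
  }
  mags <- sort(unique(c(distances$mag1, distances$mag2)))
  keep <- distances$distance <= cutoff
  gr <- igraph::graph_from_data_frame(
    distances[keep, c("mag1", "mag2"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = mags))
  comp <- igraph::components(gr)$membership
  labels <- vapply(split(names(comp), comp), function(m) min(m), "")
  out <- labels[as.character(comp)]
  names(out) <- names(comp)
  out[mags]
}

# Hydrolase family labels take the form "<type>:<family>",
# e.g. "protease:S08", "gh:GH13", "lipase:abH01".
hydrolase_families <- function(genome, type) {
  labs <- genome_labels(genome)
  pref <- paste0(type, ":")
  unique(sub(pref, "", labs[startsWith(labs, pref)], fixed = TRUE))
}

#' Capacity matrix over MAGs and species clusters
#'
#' Runs [capacity_predict()] for every MAG and pathway, then aggregates to
#' species clusters as the union of member-MAG capacities (capacities are
#' predicted per MAG first to avoid chimeric reconstructions; both levels
#' are returned). Cluster rows also carry hydrolase family counts, pathway
#' counts by class (sugar, HS/HT AA, FA), and presence of H2 generation,
#' formate generation, O2 respiration, conductive pili, multiheme
#' cytochromes and the electron-transfer complexes.
#'
#' @param genomes List of [genome_annotation()] objects (with cluster_id).
#' @param catalog Pathway catalog.
#' @param cond Conditions for the exergonicity criterion.
#' @param defs Electron-transfer definitions.
#' @param constants Constants table.
#' @param localizations Named localization vector across all genomes.
#' @return List with `per_mag` (long data.frame of capacity calls),
#'   `cluster` (cluster x capability data.frame) and `hs_ht` (pathway
#'   class lookup used for the counts).
#' @export
capacity_matrix <- function(genomes, catalog = pathway_catalog(),
                            cond = digester_conditions(),
                            defs = electron_transfer_defs(),
                            constants = formation_energies(),
                            localizations = character(0)) {
  per_mag <- do.call(rbind, lapply(genomes, function(g) {
    do.call(rbind, lapply(catalog, function(p) {
      capacity_predict(g, p, cond, defs, constants, localizations)
    }))
  }))
  rownames(per_mag) <- NULL
  clusters <- vapply(genomes, `[[`, "", "cluster_id")
  per_mag$cluster_id <- clusters[match(per_mag$mag_id,
                                       vapply(genomes, `[[`, "", "mag_id"))]

  # HS/HT class of each pathway under the same conditions (for counts)
  energ <- catalog_energetics(catalog, cond, constants)
  aa_hs <- energ$pathway[energ$substrate_class == "AA" &
                           !is.na(energ$class) & energ$class == "HS"]
  aa_ht <- energ$pathway[energ$substrate_class == "AA" &
                           !is.na(energ$class) & energ$class == "HT"]

  cl_ids <- sort(unique(clusters))
  rows <- lapply(cl_ids, function(cl) {
    members <- genomes[clusters == cl]
    caps <- per_mag[per_mag$cluster_id == cl & per_mag$capacity, "pathway"]
    caps <- unique(caps)
    sub_class <- vapply(catalog[caps], `[[`, "", "substrate_class")
    pres <- function(x) as.integer(length(x) > 0)
    enzymes <- unique(unlist(lapply(members, function(g) {
      electron_balance(g, catalog[[1]], defs, localizations)$present
    })))
    pili <- any(vapply(members, function(g) {
      ids <- genes_with_label(g, "pilA")
      any(vapply(ids, function(gid) {
        s <- g$proteins[gid]
        !is.na(s) && conductive_pili(s)
      }, logical(1)))
    }, logical(1)))
    mhc <- "mhc_eet" %in% enzymes
    data.frame(
      cluster_id = cl,
      n_mags = length(members),
      n_protease = length(unique(unlist(lapply(members, hydrolase_families,
                                               type = "protease")))),
      n_gh = length(unique(unlist(lapply(members, hydrolase_families,
                                         type = "gh")))),
      n_lipase = length(unique(unlist(lapply(members, hydrolase_families,
                                             type = "lipase")))),
      n_sugar = sum(sub_class == "sugar"),
      n_aa_hs = sum(caps %in% aa_hs),
      n_aa_ht = sum(caps %in% aa_ht),
      n_fa = sum(sub_class == "FA"),
      h2_gen = pres(intersect(enzymes, c("hyd_fefe_bif", "ech", "hyb"))),
      formate_gen = pres(intersect(enzymes, c("fdh_h", "fdh_n"))),
      o2_resp = pres(intersect(enzymes, "bd_oxidase")),
      pili = as.integer(pili),
      cytochromes = as.integer(mhc),
      rnf = as.integer("rnf" %in% enzymes),
      nfn = as.integer("nfn" %in% enzymes),
      fix = as.integer("fix" %in% enzymes),
      efd = as.integer("efd" %in% enzymes),
      flox_hdr = as.integer("flox_hdr" %in% enzymes),
      stringsAsFactors = FALSE)
  })
  cluster_tab <- do.call(rbind, rows)
  rownames(cluster_tab) <- NULL
  list(per_mag = per_mag, cluster = cluster_tab,
       hs_ht = energ[, c("pathway", "substrate_class", "class")])
}
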