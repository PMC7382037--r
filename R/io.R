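# Tab-separated, UTF-8, '.' decimal, fixed column order: bit-stable output.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a synthetic community to disk
#'
#' Emits the file formats the pipeline consumes: `annotations.tsv`
#' (mag_id, cluster_id, gene_id, contig, start, end, strand,
#' semicolon-separated labels), `proteins.fasta`, `localizations.tsv`,
#' `distances.tsv`, `expression.tsv`, `read_counts.tsv`, `domain.tsv` and
#' the ground-truth ledger `truth.tsv`.
#'
#' @param community Output of [generate_community()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- do.call(rbind, lapply(community$genomes, function(g) {
    data.frame(mag_id = g$mag_id, cluster_id = g$cluster_id,
               gene_id = g$genes$gene_id,
               contig = g$genes$contig, start = g$genes$start,
               end = g$genes$end, strand = g$genes$strand,
               labels = vapply(g$genes$labels, paste, "", collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  write_tsv(ann, file.path(dir, "annotations.tsv"))
  prots <- unlist(lapply(community$genomes, `[[`, "proteins"))
  if (length(prots) > 0) {
    names(prots) <- unlist(lapply(community$genomes,
                                  function(g) names(g$proteins)))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(prots),
                                file.path(dir, "proteins.fasta"))
  }
  if (length(community$localizations) > 0) {
    write_tsv(data.frame(gene_id = names(community$localizations),
                         localization = unname(community$localizations)),
              file.path(dir, "localizations.tsv"))
  }
  write_tsv(community$distances, file.path(dir, "distances.tsv"))
  write_tsv(as.data.frame(community$expression),
            file.path(dir, "expression.tsv"))
  write_tsv(community$read_counts, file.path(dir, "read_counts.tsv"))
  write_tsv(data.frame(cluster_id = names(community$domain),
                       domain = unname(community$domain)),
            file.path(dir, "domain.tsv"))
  write_tsv(community$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read genome annotations from a delimited table
#'
#' @param path `annotations.tsv`-style file (see [write_community()]).
#' @param proteins_fasta Optional protein FASTA keyed by gene_id.
#' @return List of [genome_annotation()] objects.
#' @export
read_annotations <- function(path, proteins_fasta = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  prots <- character(0)
  if (!is.null(proteins_fasta) && file.exists(proteins_fasta)) {
    aset <- Biostrings::readAAStringSet(proteins_fasta)
    prots <- stats::setNames(as.character(aset), names(aset))
  }
  lapply(split(tab, tab$mag_id), function(g) {
    genome_annotation(
      g$mag_id[1],
      data.frame(gene_id = g$gene_id, labels = g$labels, contig = g$contig,
                 start = g$start, end = g$end, strand = g$strand,
                 stringsAsFactors = FALSE),
      cluster_id = g$cluster_id[1],
      proteins = prots[intersect(names(prots), g$gene_id)])
  })
}

#' Orchestrate the full analysis over one community
#'
#' Runs the pipeline end to end on in-memory inputs (typically a
#' [generate_community()] output or the same structures read from disk):
#' species clustering check, per-MAG and per-cluster capacity prediction,
#' the catalog energetics table, activity calling with ECM50 consistency,
#' and the community statistics stage. Writes tab-separated outputs and a
#' machine-readable run manifest; identical inputs and config give
#' identical outputs.
#'
#' @param community Community inputs (see [generate_community()]).
#' @param out_dir Output directory; NULL for no files.
#' @param catalog Pathway catalog.
#' @param cond Conditions for capacity prediction.
#' @param defs Electron-transfer definitions.
#' @param constants Constants table.
#' @return List with `capacity`, `energetics`, `activity`, `stats`,
#'   `clusters`, `manifest`.
#' @export
run_all <- function(community, out_dir = NULL, catalog = pathway_catalog(),
                    cond = digester_conditions(),
                    defs = electron_transfer_defs(),
                    constants = formation_energies()) {
  genomes <- community$genomes
  clusters <- cluster_species(community$distances)
  # reconcile generator cluster ids with distance-derived clustering
  for (g in names(genomes)) {
    if (is.na(genomes[[g]]$cluster_id)) {
      genomes[[g]]$cluster_id <- clusters[[g]]
    }
  }
  caps <- capacity_matrix(genomes, catalog, cond, defs, constants,
                          community$localizations)
  energ <- catalog_energetics(catalog, cond, constants)
  act <- activity_matrix(genomes, caps$per_mag, community$expression,
                         community$read_counts, community$domain, catalog)

  # statistics stage on the cluster capability matrix
  feat <- caps$cluster
  num_cols <- c("n_protease", "n_gh", "n_lipase", "n_sugar", "n_aa_hs",
                "n_aa_ht", "n_fa", "h2_gen", "formate_gen", "o2_resp",
                "pili", "cytochromes", "rnf", "nfn", "fix", "efd",
                "flox_hdr")
  pear <- pearson_screen(feat[, c("n_aa_hs", "n_aa_ht", "n_gh",
                                  "n_protease", "n_fa")])
  pca <- if (nrow(feat) >= 3) {
    pca_ordinate(feat[, num_cols], scale. = TRUE)
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("ecothermo")),
    n_mags = length(genomes),
    n_clusters = length(unique(vapply(genomes, `[[`, "", "cluster_id"))),
    seed = if (!is.null(community$spec)) community$spec$seed else NA,
    config = if (!is.null(community$spec)) {
      list(noise_sigma = community$spec$noise_sigma,
           dropout = community$spec$dropout,
           reactors = length(community$spec$reactors))
    } else NULL
  )
  res <- list(capacity = caps, energetics = energ, activity = act,
              stats = list(pearson = pear, pca = pca),
              clusters = clusters, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(caps$per_mag, file.path(out_dir, "capacity_per_mag.tsv"))
    write_tsv(caps$cluster, file.path(out_dir, "capacity_cluster.tsv"))
    write_tsv(energ, file.path(out_dir, "energetics.tsv"))
    write_tsv(act$fractions, file.path(out_dir, "activity_fractions.tsv"))
    if (!is.null(act$pathway_activity)) {
      write_tsv(act$pathway_activity,
                file.path(out_dir, "pathway_activity.tsv"))
      write_tsv(act$ecm50, file.path(out_dir, "ecm50.tsv"))
    }
    write_tsv(pear, file.path(out_dir, "pearson.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
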