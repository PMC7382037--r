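# Parse "1/3"-style exact rationals from the catalog.
parse_ratio <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(as.character(x), "/", fixed = TRUE)[[1]]
  if (length(parts) == 1) return(as.numeric(parts))
  as.numeric(parts[1]) / as.numeric(parts[2])
}

#' Load the catabolic pathway catalog
#'
#' Reads the bundled (or a user-supplied) pathway catalog: for each pathway
#' the overall balanced reaction, the ordered enzyme steps (each a set of
#' alternative ortholog labels), the electron-carrier ledger, the carriers
#' whose re-oxidation must be accounted for, and the directionality class.
#' Every reaction is validated for element and charge balance against the
#' constants table on load.
#'
#' @param path Catalog file (YAML). Defaults to the bundled catalog.
#' @param constants Constants table used for reaction validation.
#' @return A named list of `pathway_def` objects.
#' @export
#' @examples
#' cat <- pathway_catalog()
#' names(cat)
pathway_catalog <- function(path = NULL, constants = formation_energies()) {
  if (is.null(path)) {
    path <- system.file("extdata", "pathway_catalog.yaml", package = "ecothermo")
  }
  raw <- yaml::read_yaml(path)
  defs <- lapply(raw$pathways, function(p) {
    st <- unlist(p$reaction)
    led_args <- p$ledger
    led_args$ion_ratio_x <- parse_ratio(led_args$ion_ratio_x)
    ledger <- do.call(carrier_ledger, led_args)
    carriers <- as.character(unlist(p$carriers_generated))
    # ledger carriers must be declared in carriers_generated (internal
    # methanogenesis ion bookkeeping in the fdh2 slot is exempt when the
    # pathway declares no external carriers)
    led_carriers <- c(NADH = ledger$nadh_gen + ledger$nadh_cons,
                      FdH2 = ledger$fdh2_gen + ledger$fdh2_cons,
                      ETFH2 = ledger$etfh2_gen + ledger$etfh2_cons,
                      quinol = ledger$quinol_gen + ledger$quinol_cons)
    used <- names(led_carriers)[led_carriers > 0]
    if (length(carriers) > 0 && !all(used %in% carriers)) {
      stop("pathway '", p$id, "': ledger uses carrier(s) not declared in ",
           "carriers_generated: ", paste(setdiff(used, carriers), collapse = ", "))
    }
    structure(list(
      id = p$id,
      name = p$name,
      substrate_class = p$substrate_class,
      canonical = isTRUE(p$canonical),
      reaction = reaction(p$id, st, constants = constants),
      ledger = ledger,
      carriers_generated = carriers,
      steps = lapply(p$steps, as.character),
      marker_steps = as.character(unlist(p$marker_steps)),
      directionality = p$directionality
    ), class = "pathway_def")
  })
  names(defs) <- vapply(defs, `[[`, "", "id")
  defs
}

#' @export
print.pathway_def <- function(x, ...) {
  cat(sprintf("<pathway> %s (%s, %s): %d steps, directionality %s\n",
              x$id, x$name, x$substrate_class, length(x$steps),
              x$directionality))
  invisible(x)
}

#' Load the electron-transfer enzyme definitions
#'
#' The edge set of the carrier re-oxidation graph: carrier and sink nodes,
#' multi-subunit complexes (credited only when co-localised) and
#' single-gene enzymes, each contributing directed edges.
#'
#' @param path Definition file (YAML). Defaults to the bundled file.
#' @return A list with `carriers`, `sinks`, `complexes`, `singles`.
#' @export
electron_transfer_defs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "electron_transfer.yaml", package = "ecothermo")
  }
  yaml::read_yaml(path)
}

#' Energetics table over the whole catalog
#'
#' Computes the standard transformed energy, ATP yield, H2 threshold and
#' HS/HT class for every pathway in the catalog under one condition set
#' (the data behind an H2-threshold panel).
#'
#' @param catalog A catalog from [pathway_catalog()].
#' @param cond A [conditions()] object.
#' @param constants Constants table.
#' @return A data.frame with one row per pathway.
#' @export
#' @examples
#' head(catalog_energetics())
catalog_energetics <- function(catalog = pathway_catalog(),
                               cond = digester_conditions(),
                               constants = formation_energies()) {
  rows <- lapply(catalog, pathway_energetics, cond = cond, constants = constants)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$substrate_class <- vapply(catalog, `[[`, "", "substrate_class")
  out
}
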