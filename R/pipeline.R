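# Command-line orchestration: a JSON-configured pipeline reproducing the
# analysis flow (ancestral inference -> event detection/tally -> optional
# identity tables, paralog ranking, degenerate scans, motif reports), with
# deterministic, sorted outputs so reruns are byte-identical. Logs go to
# stderr; machine-readable TSV/JSON go to the output directory.

pipeline_log <- function(verbose, ...) {
  if (verbose) message("[minikaryo] ", ...)
}

resolve_karyotype <- function(x) {
  if (inherits(x, "mt_karyotype")) return(x)
  if (file.exists(x)) return(read_karyotype(x))
  if (x %in% louse_karyotypes()) return(louse_karyotype(x))
  stop("cannot resolve karyotype '", x, "': not a file or fixture key")
}

#' Run the full comparative pipeline
#'
#' @param config A configuration list or path to a JSON file with elements:
#'   \describe{
#'     \item{karyotypes}{named vector/list of karyotype file paths or
#'       packaged fixture keys (see [louse_karyotypes()]).}
#'     \item{tree}{Newick file path, or `"fixture"` for the packaged tree.}
#'     \item{clades}{list of `list(name=, ingroup=, outgroup=)` ancestral
#'       inferences to run (names refer to `karyotypes` entries; the
#'       inferred ancestor joins the karyotype set under its clade name).}
#'     \item{tally_nodes}{character vector of node labels (must have
#'       karyotypes after inference) to include in the event tally.}
#'     \item{families}{optional path to a JSON taxon->family map, or
#'       `"fixture"`.}
#'   }
#' @param out_dir Output directory (created if needed).
#' @param verbose Log progress to stderr.
#' @return Invisibly, a list with the inferred ancestors, the event tally
#'   and the paths written.
#' @export
run_pipeline <- function(config, out_dir = "minikaryo_out", verbose = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  if (!is.list(config) || !length(config) || is.null(config$karyotypes)) {
    stop("usage error: config must be a list (or JSON file) with at least a 'karyotypes' entry")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  pipeline_log(verbose, "loading ", length(config$karyotypes), " karyotypes")
  karyos <- lapply(config$karyotypes, resolve_karyotype)
  if (is.null(names(karyos)) || any(!nzchar(names(karyos)))) {
    names(karyos) <- vapply(karyos, function(k) k$taxon, character(1))
  }

  tree <- NULL
  if (!is.null(config$tree)) {
    tree <- if (identical(config$tree, "fixture")) louse_tree() else
      ape::read.tree(config$tree)
  }

  ancestors <- list()
  for (cl in config$clades) {
    pipeline_log(verbose, "inferring ancestral karyotype for clade ", cl$name)
    ing <- karyos[unlist(cl$ingroup)]
    og <- if (!is.null(cl$outgroup)) karyos[[cl$outgroup]] else NULL
    anc <- infer_ancestral(unname(ing), og, clade = cl$name)
    ancestors[[cl$name]] <- anc
    karyos[[cl$name]] <- anc
    p1 <- file.path(out_dir, paste0("ancestral_", cl$name, ".txt"))
    write_karyotype(anc, p1)
    p2 <- file.path(out_dir, paste0("rule_trace_", cl$name, ".json"))
    jsonlite::write_json(anc$rule_trace, p2, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p1, p2)
  }

  tally <- NULL
  if (!is.null(tree) && !is.null(config$tally_nodes)) {
    pipeline_log(verbose, "tallying events over ",
                 length(config$tally_nodes), " karyotyped nodes")
    fams <- NULL
    if (!is.null(config$families)) {
      fams <- if (identical(config$families, "fixture")) louse_families() else
        unlist(jsonlite::read_json(config$families))
    }
    nodes <- unlist(config$tally_nodes)
    missing_k <- setdiff(nodes, names(karyos))
    if (length(missing_k)) {
      stop("configuration error: no karyotype for tally node(s): ",
           paste(missing_k, collapse = ", "))
    }
    tally <- tally_events(tree, karyos[nodes], fams)
    p1 <- file.path(out_dir, "events.tsv")
    write_events_tsv(tally$events, p1)
    p2 <- file.path(out_dir, "event_tally.json")
    jsonlite::write_json(list(by_kind = as.list(tally$by_kind),
                              total = tally$total), p2, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, p1, p2)
  }

  # human-readable summary
  sm <- file.path(out_dir, "summary.txt")
  con <- file(sm, "w")
  for (nm in names(ancestors)) {
    anc <- ancestors[[nm]]
    writeLines(sprintf("clade %s: %d inferred ancestral minichromosomes; unplaced: %s",
                       nm, length(anc$minichromosomes),
                       paste(anc$unplaced_genes, collapse = " ")), con)
  }
  if (!is.null(tally)) {
    writeLines(sprintf("events: %s",
                       paste(names(tally$by_kind), as.integer(tally$by_kind),
                             sep = "=", collapse = ", ")), con)
  }
  close(con)
  paths <- c(paths, sm)
  pipeline_log(verbose, "wrote ", length(paths), " files to ", out_dir)
  invisible(list(ancestors = ancestors, tally = tally, paths = paths))
}

#' Packaged pipeline configuration reproducing the published analysis
#'
#' The clade/tally layout used by the acceptance tests: the five seal-louse
#' fixtures under the sucking-louse MRCA, the primate-louse lineage pair,
#' and the merger-bearing branches of the published census. The twin
#' Weddell/crabeater-seal louse tips are deliberately absent from the tally
#' set (their fixture arrangements contain synthetic anchor pairings; see
#' the vignette).
#'
#' @return A configuration list for [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  karyos <- as.list(stats::setNames(louse_karyotypes(), louse_karyotypes()))
  # alias the ancestor fixtures to their tree node labels
  karyos$Anoplura_MRCA <- "MRCA_sucking_lice"
  karyos$Primate_MRCA <- "MRCA_primate_lice"
  list(
    karyotypes = karyos,
    tree = "fixture",
    families = "fixture",
    clades = list(list(name = "Echinophthiriidae_MRCA",
                       ingroup = c("A_carlinii", "A_lobodontis",
                                   "A_microchir", "L_macrorhini",
                                   "P_fluctus"),
                       outgroup = "MRCA_sucking_lice")),
    tally_nodes = c("Anoplura_MRCA", "Echinophthiriidae_MRCA",
                    "L_macrorhini", "P_fluctus", "A_microchir",
                    "Primate_MRCA", "P_pubis", "P_gorillae", "P_obtusus",
                    "H_apri")
  )
}

#' Command-line entry point
#'
#' Subcommands: `run-all <config.json> <out_dir>`,
#' `infer-ancestral <config.json> <out_dir>`, `events <config.json>
#' <out_dir>`, `simulate <seed> <out_dir>`. Machine outputs are written to
#' the output directory; logs go to stderr. Returns (invisibly) an exit
#' code: 0 on success, non-zero on usage error.
#'
#' @param args Character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @export
minikaryo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: minikaryo <run-all|infer-ancestral|events|simulate> ...")
    invisible(1L)
  }
  if (!length(args)) return(usage())
  cmd <- args[1]
  if (cmd %in% c("run-all", "infer-ancestral", "events")) {
    if (length(args) < 3L) return(usage())
    cfg <- if (identical(args[2], "default")) default_pipeline_config() else
      args[2]
    if (cmd != "run-all" && is.list(cfg)) {
      if (cmd == "infer-ancestral") cfg$tally_nodes <- NULL
      if (cmd == "events") cfg$clades <- NULL
    }
    run_pipeline(cfg, out_dir = args[3])
    return(invisible(0L))
  }
  if (cmd == "simulate") {
    if (length(args) < 3L) return(usage())
    seed <- as.integer(args[2])
    tr <- ape::read.tree(text = "((t1:0.2,t2:0.2)n2:0.2,(t3:0.2,t4:0.2)n3:0.2)n1;")
    cfg <- simulation_config(tr, louse_karyotype("MRCA_sucking_lice"),
                             seed = seed)
    sim <- simulate_karyotypes(cfg)
    dir.create(args[3], showWarnings = FALSE, recursive = TRUE)
    for (nm in names(sim$tips)) {
      write_karyotype(sim$tips[[nm]],
                      file.path(args[3], paste0(nm, ".txt")))
    }
    utils::write.table(sim$events, file.path(args[3], "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(0L))
  }
  usage()
}
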