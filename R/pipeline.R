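# End-to-end pipeline driver: evidence -> calibration -> integration ->
# evaluation, from a validated YAML/list configuration, with a provenance
# manifest and atomic (write-then-rename) outputs.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    calibrate = list(bin_size = 1000L, pseudocount = 0.5),
    integrate = list(D = 1, T = 0, decay = "linear"),
    evaluate = list(bin_size = 1000L)
  )
}

known_keys <- list(
  top = c("seed", "out_dir", "genome_size", "gold", "evidence",
          "calibrate", "integrate", "evaluate"),
  evidence = c("tag", "type", "path", "min_pairs", "corpus_size"),
  calibrate = c("bin_size", "pseudocount"),
  integrate = c("D", "T", "decay"),
  evaluate = c("bin_size")
)

check_keys <- function(cfg, allowed, where) {
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    stop("unknown config key", if (length(bad) > 1) "s", " in ", where, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

merge_defaults <- function(cfg, defaults) {
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], cfg[[nm]])
    }
  }
  cfg
}

validate_config <- function(cfg) {
  check_keys(cfg, known_keys$top, "config")
  cfg <- merge_defaults(cfg, pipeline_defaults())
  check_keys(cfg$calibrate, known_keys$calibrate, "calibrate")
  check_keys(cfg$integrate, known_keys$integrate, "integrate")
  check_keys(cfg$evaluate, known_keys$evaluate, "evaluate")
  if (is.null(cfg$gold)) stop("config must name a gold-standard GMT under 'gold'", call. = FALSE)
  if (is.null(cfg$evidence) || !length(cfg$evidence)) {
    stop("config must list >= 1 evidence input", call. = FALSE)
  }
  for (i in seq_along(cfg$evidence)) {
    ev <- cfg$evidence[[i]]
    check_keys(ev, known_keys$evidence, sprintf("evidence[%d]", i))
    if (is.null(ev$tag) || is.null(ev$type) || is.null(ev$path)) {
      stop(sprintf("evidence[%d] needs tag, type and path", i), call. = FALSE)
    }
    if (!ev$type %in% c("expression", "profiles", "citations", "scores")) {
      stop(sprintf("evidence[%d]: unknown type '%s'", i, ev$type), call. = FALSE)
    }
  }
  if (cfg$integrate$D < 1) stop("integration decay D must be >= 1", call. = FALSE)
  if (cfg$calibrate$bin_size < 2) stop("calibration bin_size must be >= 2", call. = FALSE)
  if (is.null(cfg$genome_size)) stop("config must set genome_size", call. = FALSE)
  cfg
}

# write via a temp file in the same directory, then rename: a failed stage
# never leaves a truncated output behind
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

#' Run the full network-construction pipeline from a configuration
#'
#' Stages, in dependency order: read the gold-standard pathway GMT and
#' derive positive/negative pairs; score each evidence input (expression,
#' phyletic profiles, citation index, or pre-scored pairs); calibrate each
#' to LLS and emit a data-specific network; integrate all networks by
#' weighted summation; evaluate the integrated network by a cumulative
#' precision-recall curve. All outputs are TSV under `out_dir`, written
#' atomically, plus a `manifest.json` recording the package version, the
#' fully resolved parameters, and MD5 digests of every input and output —
#' identical config and inputs therefore reproduce identical outputs.
#'
#' The configuration is a YAML file or an equivalent nested list; unknown
#' keys are rejected before any stage runs. Required keys: `gold` (pathway
#' GMT path), `evidence` (list of `{tag, type, path}` with type one of
#' `expression`, `profiles`, `citations`, `scores`) and `genome_size`.
#' Optional blocks `calibrate` (`bin_size`, `pseudocount`), `integrate`
#' (`D`, `T`, `decay`) and `evaluate` (`bin_size`) override the defaults.
#'
#' @param config Path to a YAML file, or a list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- c(cfg$gold, vapply(cfg$evidence, `[[`, "", "path"))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) stop("missing input file(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)

  message("[gold] deriving gold standard from ", cfg$gold)
  gold <- gold_from_annotations(read_gmt(cfg$gold))
  message(sprintf("[gold] %d positives, %d negatives",
                  nrow(gold$positives), nrow(gold$negatives)))

  nets <- list()
  stages <- list()
  for (ev_cfg in cfg$evidence) {
    tag <- ev_cfg$tag
    ev <- switch(ev_cfg$type,
      expression = coexpression_scores(read_expression(ev_cfg$path),
                                       min_pairs = ev_cfg$min_pairs %||% 10L),
      profiles = phyletic_scores(read_profiles(ev_cfg$path)),
      citations = cocitation_scores(read_citations(ev_cfg$path,
                                                   ev_cfg$corpus_size)),
      scores = read_evidence(ev_cfg$path, tag = tag))
    attr(ev, "tag") <- tag
    model <- calibrate(ev, gold, bin_size = cfg$calibrate$bin_size,
                       pseudocount = cfg$calibrate$pseudocount)
    net <- apply_calibration(model, ev)
    message(sprintf("[evidence %s] %d scored pairs -> %d links with LLS > 0",
                    tag, nrow(ev), nrow(net)))
    atomic_write(function(p) write_calibration(model, p),
                 file.path(out_dir, paste0("calibration_", tag, ".tsv")))
    atomic_write(function(p) write_edge_list(net, p),
                 file.path(out_dir, paste0("network_", tag, ".tsv")))
    nets[[tag]] <- net
    stages[[paste0("evidence_", tag)]] <-
      list(scored_pairs = nrow(ev), links = nrow(net))
  }

  integrated <- integrate_networks(nets, D = cfg$integrate$D,
                                   T_ = cfg$integrate$T,
                                   decay = cfg$integrate$decay)
  message(sprintf("[integrate] %d links over %d genes (D=%g, T=%g)",
                  nrow(integrated), length(network_genes(integrated)),
                  cfg$integrate$D, cfg$integrate$T))
  atomic_write(function(p) write_edge_list(integrated, p),
               file.path(out_dir, "network_integrated.tsv"))
  stages$integrate <- list(links = nrow(integrated),
                           genes = length(network_genes(integrated)))

  pr <- pr_curve(integrated, gold, bin_size = cfg$evaluate$bin_size,
                 genome_size = cfg$genome_size)
  atomic_write(function(p) utils::write.table(pr, p, sep = "\t", quote = FALSE,
                                              row.names = FALSE),
               file.path(out_dir, "pr_integrated.tsv"))
  stages$evaluate <- list(pr_points = nrow(pr), pr_area = pr_area(pr))

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "funclink",
    version = as.character(utils::packageVersion("funclink")),
    parameters = cfg,
    stages = stages,
    input_md5 = as.list(tools::md5sum(inputs)),
    output_md5 = as.list(tools::md5sum(sort(outputs)))
  )
  atomic_write(function(p) jsonlite::write_json(manifest, p, auto_unbox = TRUE,
                                                pretty = TRUE, digits = NA),
               file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
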