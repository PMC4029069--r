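#' Pipeline configuration
#'
#' Collects inputs and thresholds for [run_pipeline()] and validates them
#' on construction.  Every input may be a path to a TSV file (read with
#' the package's readers) or an already-loaded data frame.  The default
#' thresholds are the conventional ones for this analysis: DEG calls at
#' `|log2FC| >= 1` and `FDR < 0.001`, consensus membership `n_min = 6`
#' of the 12 cross comparisons, background exclusion at >= 5 of 6
#' within-tolerant and >= 2 of 3 within-sensitive pairs, and enrichment
#' at raw `p <= 0.05`.
#'
#' @param counts Counts table or path.
#' @param design Sample design table or path.
#' @param out_dir Output directory for the report bundle.
#' @param gene_lengths Optional gene-length table or path (enables the
#'   RPKM/log2/genotype-mean expression report).
#' @param go_annotation,pathway_annotation Optional flat annotation
#'   tables or paths for enrichment.
#' @param qpcr_ct Optional CT table or path for qPCR validation.
#' @param qpcr_control_gene,qpcr_test_genotype,qpcr_reference_genotype
#'   qPCR analysis settings; genotypes default to the design's first
#'   sensitive and first tolerant genotype so that the qPCR fold change
#'   shares the `log2(sensitive/tolerant)` orientation.
#' @param lfc_threshold,fdr_threshold DEG significance cutoffs.
#' @param n_min Consensus membership threshold.
#' @param tolerant_exclude_min,sensitive_exclude_min Within-group
#'   exclusion thresholds.
#' @param enrich_alpha Enrichment significance level.
#' @param pseudocount log2 pseudocount for the expression report.
#' @param prior_count Fold-change prior count.
#' @param ns_marker Non-significant cell marker in the consensus table.
#' @param seed Optional integer recorded in the run manifest (the
#'   pipeline itself is deterministic).
#'
#' @return A list of class `ndeg_config`.
#' @export
pipeline_config <- function(counts, design, out_dir,
                            gene_lengths = NULL,
                            go_annotation = NULL, pathway_annotation = NULL,
                            qpcr_ct = NULL, qpcr_control_gene = NULL,
                            qpcr_test_genotype = NULL,
                            qpcr_reference_genotype = NULL,
                            lfc_threshold = 1, fdr_threshold = 0.001,
                            n_min = 6,
                            tolerant_exclude_min = 5, sensitive_exclude_min = 2,
                            enrich_alpha = 0.05,
                            pseudocount = 1, prior_count = 0.125,
                            ns_marker = "ns", seed = NULL) {
  check_pos <- function(x, field, lo = 0, hi = Inf, strict_lo = TRUE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
        (strict_lo && x <= lo) || (!strict_lo && x < lo) || x > hi) {
      stop_param(sprintf("`%s` out of range.", field), field = field)
    }
    x
  }
  check_pos(lfc_threshold, "lfc_threshold", 0, Inf, strict_lo = FALSE)
  check_pos(fdr_threshold, "fdr_threshold", 0, 1)
  check_pos(n_min, "n_min", 1, Inf, strict_lo = FALSE)
  check_pos(tolerant_exclude_min, "tolerant_exclude_min", 1, Inf, strict_lo = FALSE)
  check_pos(sensitive_exclude_min, "sensitive_exclude_min", 1, Inf, strict_lo = FALSE)
  check_pos(enrich_alpha, "enrich_alpha", 0, 1)
  check_pos(pseudocount, "pseudocount", 0)
  check_pos(prior_count, "prior_count", 0)
  if (!ns_marker %in% c("ns", "**")) {
    stop_param("`ns_marker` must be 'ns' or '**'.", field = "ns_marker")
  }
  structure(
    list(
      counts = counts, design = design, out_dir = out_dir,
      gene_lengths = gene_lengths,
      go_annotation = go_annotation, pathway_annotation = pathway_annotation,
      qpcr_ct = qpcr_ct, qpcr_control_gene = qpcr_control_gene,
      qpcr_test_genotype = qpcr_test_genotype,
      qpcr_reference_genotype = qpcr_reference_genotype,
      lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold,
      n_min = n_min,
      tolerant_exclude_min = tolerant_exclude_min,
      sensitive_exclude_min = sensitive_exclude_min,
      enrich_alpha = enrich_alpha,
      pseudocount = pseudocount, prior_count = prior_count,
      ns_marker = ns_marker, seed = seed
    ),
    class = "ndeg_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; path-valued
#' entries are resolved relative to the YAML file's directory.
#'
#' @param path Path to a YAML configuration.
#' @return A validated `ndeg_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  path_fields <- c("counts", "design", "gene_lengths", "go_annotation",
                   "pathway_annotation", "qpcr_ct", "out_dir")
  for (f in intersect(path_fields, names(cfg))) {
    if (is.character(cfg[[f]]) && !grepl("^/", cfg[[f]])) {
      cfg[[f]] <- file.path(base, cfg[[f]])
    }
  }
  do.call(pipeline_config, cfg)
}

load_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full consensus differential-expression pipeline
#'
#' Orchestrates the analysis end to end: pairwise NB exact tests over the
#' whole comparison grid, membership counting, within-group exclusion,
#' the consensus list with direction classes, optional enrichment of the
#' sensitive- and tolerant-abundant lists against GO and pathway
#' annotations, an optional expression report (RPKM, log2, genotype
#' means) and optional qPCR validation.  All result tables are written as
#' TSV under `config$out_dir` together with a JSON run manifest; reruns
#' with the same configuration reproduce the outputs byte for byte.
#'
#' Any stage failure aborts with the stage name and the underlying cause.
#'
#' @param config An `ndeg_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`comparisons`,
#'   `consensus`, `exclusions`, `enrichment`, `expression`, `qpcr`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ndeg_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "ndeg_pipeline_error", parent = e)
    })
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  counts <- stage("read counts", load_input(config$counts, read_count_matrix))
  design <- stage("read design", check_design(load_input(config$design, read_design)))

  grid <- stage("enumerate comparisons", enumerate_comparisons(design))
  results <- stage("differential expression", run_comparisons(
    counts, design, grid,
    lfc_threshold = config$lfc_threshold, fdr_threshold = config$fdr_threshold,
    prior_count = config$prior_count
  ))
  stage("write DE tables", for (lab in names(results)) {
    fn <- file.path(out_dir, paste0("de_", gsub("/", "_vs_", lab), ".tsv"))
    write_table(tibble::as_tibble(results[[lab]]), fn)
  })

  types <- grid$type
  cross <- results[types == "cross"]
  excl <- stage("within-group exclusion", within_group_exclusion(
    results[types == "within_tolerant"],
    results[types == "within_sensitive"],
    tolerant_min = config$tolerant_exclude_min,
    sensitive_min = config$sensitive_exclude_min
  ))
  cons <- stage("consensus", build_consensus(cross, excl, n_min = config$n_min))
  stage("write consensus tables", {
    write_table(cons$histogram, file.path(out_dir, "membership_histogram.tsv"))
    write_table(excl[excl$excluded, ], file.path(out_dir, "exclusions.tsv"))
    write_table(cons$common, file.path(out_dir, "common_degs.tsv"))
    write_table(format_consensus_table(cons, marker = config$ns_marker),
                file.path(out_dir, "consensus_table.tsv"))
  })

  enrichment <- list()
  stage("enrichment", {
    annos <- list(
      go = load_input(config$go_annotation, read_annotation),
      pathway = load_input(config$pathway_annotation, read_annotation)
    )
    lists <- list(
      sensitive_abundant = cons$common$gene_id[
        cons$common$direction == "sensitive_abundant"],
      tolerant_abundant = cons$common$gene_id[
        cons$common$direction == "tolerant_abundant"]
    )
    for (a in names(annos)) {
      if (is.null(annos[[a]])) next
      for (l in names(lists)) {
        if (length(lists[[l]]) == 0) next
        key <- paste(a, l, sep = "_")
        enrichment[[key]] <- enrich(lists[[l]], annos[[a]],
                                    alpha = config$enrich_alpha)
        write_table(enrichment[[key]],
                    file.path(out_dir, paste0("enrichment_", key, ".tsv")))
      }
    }
  })

  expression <- NULL
  stage("expression report", {
    glen <- load_input(config$gene_lengths, read_gene_lengths)
    if (!is.null(glen)) {
      expression <- average_replicates(
        log_transform(rpkm(counts, glen), pseudocount = config$pseudocount),
        design
      )
      write_table(expression, file.path(out_dir, "genotype_mean_log2rpkm.tsv"))
    }
  })

  qpcr <- NULL
  stage("qPCR validation", {
    ct <- load_input(config$qpcr_ct, function(p) {
      read_ct_table(p, control_gene = config$qpcr_control_gene)
    })
    if (!is.null(ct)) {
      gt <- dplyr::distinct(design, .data$genotype, .data$group)
      test_g <- config$qpcr_test_genotype %||%
        gt$genotype[gt$group == "sensitive"][1]
      ref_g <- config$qpcr_reference_genotype %||%
        gt$genotype[gt$group == "tolerant"][1]
      report <- qpcr_report(ct, test_g, ref_g,
                            control_gene = config$qpcr_control_gene)
      write_table(report, file.path(out_dir, "qpcr_report.tsv"))
      lab <- paste(genotype_label(design, test_g),
                   genotype_label(design, ref_g), sep = "/")
      rnaseq <- if (lab %in% names(cross)) {
        cross[[lab]]
      } else {
        results[[which(vapply(results, attr, "", "comparison") == lab)[1]]]
      }
      conc <- compare_to_rnaseq(report, rnaseq)
      write_table(conc$per_gene, file.path(out_dir, "concordance.tsv"))
      write_table(glance(conc), file.path(out_dir, "concordance_summary.tsv"))
      qpcr <- list(report = report, concordance = conc)
    }
  })

  stage("manifest", {
    manifest <- list(
      package = "ndeg",
      version = as.character(packageVersion("ndeg")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      thresholds = list(
        lfc = config$lfc_threshold, fdr = config$fdr_threshold,
        n_min = config$n_min,
        tolerant_exclude_min = config$tolerant_exclude_min,
        sensitive_exclude_min = config$sensitive_exclude_min,
        enrich_alpha = config$enrich_alpha,
        pseudocount = config$pseudocount, prior_count = config$prior_count
      ),
      inputs = lapply(
        config[c("counts", "design", "gene_lengths", "go_annotation",
                 "pathway_annotation", "qpcr_ct")],
        function(x) if (is.character(x)) x else if (is.null(x)) NULL else "<in-memory>"
      ),
      comparisons = names(results)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  })

  invisible(list(
    comparisons = results, consensus = cons, exclusions = excl,
    enrichment = enrichment, expression = expression, qpcr = qpcr
  ))
}
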