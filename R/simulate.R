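#' Default genotype panel for simulations
#'
#' Seven sorghum genotypes split into the two nitrogen-stress response
#' groups used throughout the package: three low-N-sensitive lines (CK60,
#' BTx623 and the low-NUE RIL bulk) and four low-N-tolerant lines (San Chi
#' San, China17, KS78 and the high-NUE RIL bulk).  The `alias` column
#' carries the conventional 1-7 library numbering used in comparison
#' labels such as `"1/3"`.
#'
#' @return A tibble with columns `genotype`, `group` and `alias`.
#' @export
#' @examples
#' default_genotypes()
default_genotypes <- function() {
  tibble::tibble(
    genotype = c("CK60", "BTx623", "SanChiSan", "China17", "KS78",
                 "highNUE", "lowNUE"),
    group = c("sensitive", "sensitive", "tolerant", "tolerant", "tolerant",
              "tolerant", "sensitive"),
    alias = as.character(1:7)
  )
}

#' Simulation parameters for synthetic RNA-seq counts
#'
#' Bundles and validates every knob of the count generator.  Defaults
#' emulate the structure of a seven-genotype root transcriptome study:
#' 7 genotypes (3 sensitive, 4 tolerant) with 4 biological replicates
#' each, a few thousand expressed genes, negative-binomial count noise,
#' and three planted gene classes -- group-consistent tolerance DEGs (up
#' in tolerant or up in sensitive genotypes) and genotype-idiosyncratic
#' background DEGs that perturb exactly one genotype.
#'
#' @param n_genes Number of genes.
#' @param genotypes Data frame with columns `genotype` and `group`
#'   (`"sensitive"`/`"tolerant"`), optionally `alias`.  At least two
#'   genotypes per group are required so within-group comparisons exist.
#' @param n_replicates Biological replicates per genotype (>= 2).
#' @param mean_log2_expression Length-2 numeric `(location, scale)` of the
#'   normal distribution of per-gene log2 relative abundance.
#' @param dispersion Negative-binomial dispersion phi >= 0, with
#'   `variance = mu + phi * mu^2`; `0` gives Poisson counts.
#' @param library_size_range Length-2 range of per-sample sequencing
#'   depths (reads), drawn uniformly.
#' @param gene_length_range Length-2 range of gene lengths (bp), uniform.
#' @param n_tolerance_degs_up_tolerant,n_tolerance_degs_up_sensitive
#'   Numbers of planted group-consistent tolerance DEGs, elevated in all
#'   tolerant (resp. all sensitive) genotypes.
#' @param n_background_degs Number of planted background DEGs, each
#'   perturbing exactly one randomly chosen genotype with a random sign.
#' @param planted_log2fc Magnitude of every planted log2 effect.
#' @param seed Integer seed; identical parameters and seed reproduce the
#'   simulation bitwise.
#'
#' @return A validated list of class `ndeg_sim_params`.
#' @seealso [simulate_counts()]
#' @export
sim_params <- function(n_genes = 5000,
                       genotypes = default_genotypes(),
                       n_replicates = 4,
                       mean_log2_expression = c(location = 4, scale = 2),
                       dispersion = 0.1,
                       library_size_range = c(5e5, 1e6),
                       gene_length_range = c(500, 5000),
                       n_tolerance_degs_up_tolerant = 100,
                       n_tolerance_degs_up_sensitive = 100,
                       n_background_degs = 200,
                       planted_log2fc = 2,
                       seed = 1L) {
  check_count <- function(x, field, min = 0) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
      stop_param(sprintf("`%s` must be a single integer >= %d.", field, min),
                 field = field)
    }
    as.integer(x)
  }
  n_genes <- check_count(n_genes, "n_genes", 1)
  n_replicates <- check_count(n_replicates, "n_replicates", 2)
  nut <- check_count(n_tolerance_degs_up_tolerant, "n_tolerance_degs_up_tolerant")
  nus <- check_count(n_tolerance_degs_up_sensitive, "n_tolerance_degs_up_sensitive")
  nbg <- check_count(n_background_degs, "n_background_degs")
  if (nut + nus + nbg > n_genes) {
    stop_param("planted class counts must sum to at most `n_genes`.",
               field = "n_genes")
  }
  if (!is.data.frame(genotypes) ||
      !all(c("genotype", "group") %in% names(genotypes))) {
    stop_param("`genotypes` must have columns `genotype` and `group`.",
               field = "genotypes")
  }
  if (anyDuplicated(genotypes$genotype)) {
    stop_param("`genotypes$genotype` must be unique.", field = "genotypes")
  }
  if (sum(genotypes$group == "sensitive") < 2 ||
      sum(genotypes$group == "tolerant") < 2) {
    stop_param(paste0(
      "`genotypes` needs at least 2 sensitive and 2 tolerant genotypes ",
      "so that within-group comparisons exist."
    ), field = "genotypes")
  }
  check_range <- function(x, field, positive = TRUE) {
    if (!is.numeric(x) || length(x) != 2 || anyNA(x) || x[1] > x[2] ||
        (positive && x[1] <= 0)) {
      stop_param(sprintf("`%s` must be a non-decreasing positive length-2 range.",
                         field), field = field)
    }
    as.numeric(x)
  }
  library_size_range <- check_range(library_size_range, "library_size_range")
  gene_length_range <- check_range(gene_length_range, "gene_length_range")
  if (!is.numeric(mean_log2_expression) || length(mean_log2_expression) != 2 ||
      anyNA(mean_log2_expression) || mean_log2_expression[2] < 0) {
    stop_param("`mean_log2_expression` must be `(location, scale)` with scale >= 0.",
               field = "mean_log2_expression")
  }
  if (!is.numeric(dispersion) || length(dispersion) != 1 ||
      is.na(dispersion) || dispersion < 0) {
    stop_param("`dispersion` must be a single number >= 0.", field = "dispersion")
  }
  if (!is.numeric(planted_log2fc) || length(planted_log2fc) != 1 ||
      is.na(planted_log2fc) || planted_log2fc < 0) {
    stop_param("`planted_log2fc` must be a single number >= 0.",
               field = "planted_log2fc")
  }
  seed <- check_count(seed, "seed")
  structure(
    list(
      n_genes = n_genes,
      genotypes = tibble::as_tibble(genotypes),
      n_replicates = n_replicates,
      mean_log2_expression = as.numeric(mean_log2_expression),
      dispersion = as.numeric(dispersion),
      library_size_range = library_size_range,
      gene_length_range = gene_length_range,
      n_tolerance_degs_up_tolerant = nut,
      n_tolerance_degs_up_sensitive = nus,
      n_background_degs = nbg,
      planted_log2fc = as.numeric(planted_log2fc),
      seed = seed
    ),
    class = "ndeg_sim_params"
  )
}

#' Simulate a count matrix with planted tolerance and background DEGs
#'
#' Draws gene-level read counts for every genotype/replicate library.  Per
#' gene `g` and sample `s` the mean is `mu = L_s * p_g * 2^delta`, where
#' `L_s` is the library size, `p_g` the gene's relative abundance
#' (log2-normal across genes, normalized to sum to one) and `delta` the
#' planted log2 effect of the sample's genotype; counts are negative
#' binomial with dispersion `phi` (`variance = mu + phi * mu^2`), Poisson
#' when `phi = 0`.
#'
#' Planted classes: `tolerance_up_tolerant` genes carry `+planted_log2fc`
#' in every tolerant genotype, `tolerance_up_sensitive` in every sensitive
#' genotype, and `background` genes carry a random-sign effect in exactly
#' one random genotype, mimicking expression differences that reflect
#' genotype background rather than stress tolerance.
#'
#' @param params A [sim_params()] object.
#'
#' @return A list of class `ndeg_sim` with tibbles `counts` (gene_id +
#'   one column per sample, named `genotype.replicate`), `design`
#'   (sample_id, genotype, group, replicate and alias when provided),
#'   `genes` (gene_id, length_bp) and `truth` (gene_id, class,
#'   affected_genotypes, effect_log2, true_log2fc), plus the `params`.
#'   `true_log2fc` is oriented as log2(sensitive/tolerant); `effect_log2`
#'   is the signed effect applied to the affected genotypes.
#' @export
#' @examples
#' sim <- simulate_counts(sim_params(n_genes = 200, seed = 7))
#' sim$counts[1:3, 1:4]
#' table(sim$truth$class)
simulate_counts <- function(params) {
  if (!inherits(params, "ndeg_sim_params")) {
    stop_param("`params` must be created by `sim_params()`.")
  }
  set.seed(params$seed)
  ng <- params$n_genes
  gt <- params$genotypes
  gene_id <- sprintf("G%05d", seq_len(ng))

  loc <- params$mean_log2_expression[1]
  sc <- params$mean_log2_expression[2]
  abundance <- 2^rnorm(ng, loc, sc)
  p <- abundance / sum(abundance)
  len <- round(runif(ng, params$gene_length_range[1], params$gene_length_range[2]))

  # Planted truth -----------------------------------------------------------
  cls <- rep("null", ng)
  n_planted <- params$n_tolerance_degs_up_tolerant +
    params$n_tolerance_degs_up_sensitive + params$n_background_degs
  planted_idx <- if (n_planted > 0) sample(ng, n_planted) else integer(0)
  i_ut <- planted_idx[seq_len(params$n_tolerance_degs_up_tolerant)]
  i_us <- planted_idx[params$n_tolerance_degs_up_tolerant +
                        seq_len(params$n_tolerance_degs_up_sensitive)]
  i_bg <- planted_idx[params$n_tolerance_degs_up_tolerant +
                        params$n_tolerance_degs_up_sensitive +
                        seq_len(params$n_background_degs)]
  cls[i_ut] <- "tolerance_up_tolerant"
  cls[i_us] <- "tolerance_up_sensitive"
  cls[i_bg] <- "background"

  tol_geno <- gt$genotype[gt$group == "tolerant"]
  sens_geno <- gt$genotype[gt$group == "sensitive"]
  delta <- matrix(0, ng, nrow(gt), dimnames = list(gene_id, gt$genotype))
  fc <- params$planted_log2fc
  delta[i_ut, tol_geno] <- fc
  delta[i_us, sens_geno] <- fc
  bg_geno <- sample(gt$genotype, length(i_bg), replace = TRUE)
  bg_sign <- sample(c(-1, 1), length(i_bg), replace = TRUE)
  for (k in seq_along(i_bg)) delta[i_bg[k], bg_geno[k]] <- bg_sign[k] * fc

  affected <- rep("", ng)
  affected[i_ut] <- paste(tol_geno, collapse = ";")
  affected[i_us] <- paste(sens_geno, collapse = ";")
  affected[i_bg] <- bg_geno
  effect <- rep(0, ng)
  effect[c(i_ut, i_us)] <- fc
  effect[i_bg] <- bg_sign * fc
  true_lfc <- rep(0, ng)
  true_lfc[i_ut] <- -fc
  true_lfc[i_us] <- fc
  bg_sensitive <- bg_geno %in% sens_geno
  true_lfc[i_bg] <- ifelse(bg_sensitive, bg_sign * fc, -bg_sign * fc)

  # Libraries ---------------------------------------------------------------
  design <- tidyr::expand_grid(
    genotype = gt$genotype,
    replicate = seq_len(params$n_replicates)
  )
  design <- dplyr::mutate(
    design,
    sample_id = paste(.data$genotype, .data$replicate, sep = "."),
    group = gt$group[match(.data$genotype, gt$genotype)]
  )
  if ("alias" %in% names(gt)) {
    design$alias <- gt$alias[match(design$genotype, gt$genotype)]
  }
  design <- dplyr::select(design, dplyr::any_of(
    c("sample_id", "genotype", "group", "replicate", "alias")
  ))
  ns <- nrow(design)
  lib <- round(runif(ns, params$library_size_range[1], params$library_size_range[2]))

  mu <- (p %o% lib) * 2^delta[, design$genotype, drop = FALSE]
  counts <- if (params$dispersion > 0) {
    matrix(rnbinom(ng * ns, mu = mu, size = 1 / params$dispersion), ng, ns)
  } else {
    matrix(rpois(ng * ns, mu), ng, ns)
  }
  colnames(counts) <- design$sample_id

  structure(
    list(
      counts = tibble::as_tibble(cbind(tibble::tibble(gene_id = gene_id),
                                       tibble::as_tibble(counts))),
      design = design,
      genes = tibble::tibble(gene_id = gene_id, length_bp = len),
      truth = tibble::tibble(
        gene_id = gene_id, class = cls, affected_genotypes = affected,
        effect_log2 = effect, true_log2fc = true_lfc
      ),
      params = params
    ),
    class = "ndeg_sim"
  )
}

#' @export
print.ndeg_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic RNA-seq data: %d genes x %d samples (%d genotypes x %d replicates)\n",
    nrow(x$counts), nrow(x$design),
    length(unique(x$design$genotype)), x$params$n_replicates
  ))
  print(table(x$truth$class))
  invisible(x)
}

#' Generate a synthetic term-to-gene annotation with enriched terms
#'
#' Builds a flat gene-set annotation (GO-term or pathway style) over the
#' simulated gene universe.  A fraction of terms is designated "enriched":
#' each of their members is drawn from the planted DEG classes with
#' probability `enrichment_strength` and uniformly from the whole universe
#' otherwise, so `enrichment_strength = 0` gives membership independent of
#' gene class and `enrichment_strength = 1` makes enriched terms pure
#' planted-DEG sets.
#'
#' @param truth The `truth` tibble from [simulate_counts()].
#' @param n_terms Number of terms; `0` returns an empty annotation with a
#'   warning.
#' @param enrichment_strength Probability in `[0, 1]` that a member of an
#'   enriched term is drawn from the planted classes.
#' @param seed Integer seed.
#' @param term_size_range Length-2 range of term sizes (genes per term).
#' @param prop_enriched Fraction of terms designated enriched.
#'
#' @return A tibble with columns `term_id`, `term_name`, `gene_id` and
#'   attributes `universe` (all gene ids) and `enriched_terms` (ids of the
#'   terms constructed as enriched).
#' @export
make_annotation <- function(truth, n_terms = 100, enrichment_strength = 0.5,
                            seed = 1L, term_size_range = c(10, 40),
                            prop_enriched = 0.2) {
  if (!is.numeric(enrichment_strength) || length(enrichment_strength) != 1 ||
      is.na(enrichment_strength) || enrichment_strength < 0 ||
      enrichment_strength > 1) {
    stop_param("`enrichment_strength` must be a single number in [0, 1].",
               field = "enrichment_strength")
  }
  if (!is.data.frame(truth) || !all(c("gene_id", "class") %in% names(truth))) {
    stop_param("`truth` must have columns `gene_id` and `class`.", field = "truth")
  }
  universe <- truth$gene_id
  empty <- tibble::tibble(term_id = character(), term_name = character(),
                          gene_id = character())
  if (n_terms == 0) {
    warn("`n_terms` is 0; returning an empty annotation.")
    attr(empty, "universe") <- universe
    attr(empty, "enriched_terms") <- character(0)
    return(empty)
  }
  set.seed(seed)
  planted <- truth$gene_id[truth$class != "null"]
  n_enriched <- if (length(planted) > 0) round(prop_enriched * n_terms) else 0L
  sizes <- sample(seq(term_size_range[1], term_size_range[2]), n_terms,
                  replace = TRUE)
  sizes <- pmin(sizes, length(universe))
  term_id <- sprintf("T%04d", seq_len(n_terms))
  rows <- purrr::map(seq_len(n_terms), function(i) {
    size <- sizes[i]
    if (i <= n_enriched) {
      k <- min(rbinom(1, size, enrichment_strength), length(planted))
      from_planted <- sample(planted, k)
      rest <- sample(setdiff(universe, from_planted), size - k)
      members <- c(from_planted, rest)
    } else {
      members <- sample(universe, size)
    }
    tibble::tibble(
      term_id = term_id[i],
      term_name = sprintf("synthetic term %d", i),
      gene_id = sort(members)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "universe") <- universe
  attr(out, "enriched_terms") <- term_id[seq_len(n_enriched)]
  out
}

#' Simulate a qPCR threshold-cycle (CT) table
#'
#' Emits CT values consistent with the planted truth: for gene `g` in
#' genotype `j`, `CT = intercept - delta_g(j) + noise`, where `delta_g(j)`
#' is the planted log2 effect of genotype `j` on gene `g` (one extra cycle
#' per halving of expression).  The control gene must be a null gene so
#' its expected CT is constant across genotypes, as required of a
#' reference gene.
#'
#' @param truth The `truth` tibble from [simulate_counts()].
#' @param genotypes Data frame with columns `genotype` and `group` (a
#'   simulation design or [default_genotypes()]).
#' @param selected_genes Gene ids to assay alongside the control.
#' @param control_gene Id of the reference gene; must have class `"null"`.
#' @param ct_noise_sd Gaussian noise SD in cycles; `0` gives exact CTs.
#' @param n_replicates Replicates per gene/genotype.
#' @param intercept Baseline CT (cycles).
#' @param seed Integer seed.
#'
#' @return A tibble `(gene_id, genotype, replicate, ct)` with attribute
#'   `control_gene`.
#' @seealso [delta_delta_ct()]
#' @export
simulate_ct_table <- function(truth, genotypes, selected_genes, control_gene,
                              ct_noise_sd = 0.2, n_replicates = 3,
                              intercept = 25, seed = 1L) {
  genes <- unique(c(selected_genes, control_gene))
  missing <- setdiff(genes, truth$gene_id)
  if (length(missing) > 0) {
    stop_param(sprintf("genes not present in `truth`: %s.",
                       paste(missing, collapse = ", ")))
  }
  ctrl_class <- truth$class[truth$gene_id == control_gene]
  if (ctrl_class != "null") {
    stop_param(sprintf(
      "control gene '%s' has a planted effect (class '%s'); a reference gene must be expression-stable across genotypes.",
      control_gene, ctrl_class
    ), field = "control_gene")
  }
  if (!is.numeric(ct_noise_sd) || ct_noise_sd < 0) {
    stop_param("`ct_noise_sd` must be >= 0.", field = "ct_noise_sd")
  }
  set.seed(seed)
  tab <- tidyr::expand_grid(
    gene_id = genes,
    genotype = genotypes$genotype,
    replicate = seq_len(n_replicates)
  )
  idx <- match(tab$gene_id, truth$gene_id)
  aff <- strsplit(truth$affected_genotypes[idx], ";", fixed = TRUE)
  hit <- purrr::map2_lgl(aff, tab$genotype, function(a, g) g %in% a)
  delta <- ifelse(hit, truth$effect_log2[idx], 0)
  tab$ct <- intercept - delta +
    if (ct_noise_sd > 0) rnorm(nrow(tab), 0, ct_noise_sd) else 0
  attr(tab, "control_gene") <- control_gene
  tab
}
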