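#' Pipeline configuration
#'
#' Collects the stage inputs (synthetic specs by default; file paths
#' may replace any of them) and every analysis threshold in one
#' object. Defaults are the thresholds used throughout the package:
#' FDR 0.10 for chimera-biased labeling, enrichment alpha 0.05,
#' reporting window (8, 400) exclusive and term-median window
#' 13 to 399 inclusive, 10000 permutations, finite-difference step
#' 0.1, overlap fraction 0.3, low-count threshold 4 reads per library,
#' correlation cap 0.90. A master seed derives one independent seed
#' per stage.
#'
#' @param counts_spec a [count_sim_spec()], or `NULL` with
#'   `counts_path`/`metadata_path` set.
#' @param annotation_spec an [annotation_sim_spec()], or `NULL` with
#'   `terms_path`/`annotations_path` set.
#' @param timecourse_spec a [timecourse_sim_spec()].
#' @param scene_spec a [scene_sim_spec()].
#' @param counts_path,metadata_path,terms_path,annotations_path
#'   optional file-based inputs replacing the corresponding spec.
#' @param fdr_threshold,enrich_alpha,enrich_window,median_window,n_perm
#'   analysis thresholds (see description).
#' @param fd_step,overlap_frac,low_count_threshold,cor_cap more
#'   thresholds: finite-difference step, tracking overlap fraction,
#'   filtering threshold, shape-parameter correlation cap.
#' @param query_times staging ground truth: reference time indices at
#'   which clonal and chimeric query samples are drawn.
#' @param seed master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_spec = count_sim_spec(),
                            annotation_spec = annotation_sim_spec(),
                            timecourse_spec = timecourse_sim_spec(),
                            scene_spec = NULL,
                            counts_path = NULL, metadata_path = NULL,
                            terms_path = NULL, annotations_path = NULL,
                            fdr_threshold = 0.10,
                            enrich_alpha = 0.05,
                            enrich_window = c(8, 400),
                            median_window = c(13, 399),
                            n_perm = 10000,
                            fd_step = 0.1,
                            overlap_frac = 0.3,
                            low_count_threshold = 4,
                            cor_cap = 0.90,
                            query_times = c(clonal = 11, chimeric = 10),
                            seed = 1L) {
  if (is.null(scene_spec)) {
    scene_spec <- scene_sim_spec(
      frame_shape = c(300, 300), n_frames = 4, n_aggregates = 6,
      event_script = data.frame(frame = c(2, 2), id = c(1, 3),
                                type = c("split", "merge"),
                                partner = c(NA, 4)),
      seed = derive_seed(seed, "scene-spec"))
  }
  stopifnot(fdr_threshold > 0, fdr_threshold < 1,
            enrich_alpha >= 0, enrich_alpha < 1,
            n_perm >= 1, fd_step > 0,
            overlap_frac > 0, overlap_frac <= 1,
            low_count_threshold >= 0, cor_cap > 0, cor_cap <= 1)
  structure(list(counts_spec = counts_spec, annotation_spec = annotation_spec,
                 timecourse_spec = timecourse_spec, scene_spec = scene_spec,
                 counts_path = counts_path, metadata_path = metadata_path,
                 terms_path = terms_path, annotations_path = annotations_path,
                 fdr_threshold = fdr_threshold, enrich_alpha = enrich_alpha,
                 enrich_window = enrich_window, median_window = median_window,
                 n_perm = n_perm, fd_step = fd_step,
                 overlap_frac = overlap_frac,
                 low_count_threshold = low_count_threshold, cor_cap = cor_cap,
                 query_times = query_times, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Loads a declarative configuration: top-level keys matching the
#' arguments of [pipeline_config()] (thresholds, seed, input paths),
#' plus optional `counts_spec`, `annotation_spec`, `timecourse_spec`
#' and `scene_spec` blocks whose keys are passed to the corresponding
#' spec constructors.
#'
#' @param path path to a YAML file.
#' @return A [pipeline_config()].
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("seed: 9", "n_perm: 500",
#'              "counts_spec: {n_genes: 200, n_de: 10}"), f)
#' cfg <- read_pipeline_config(f)
#' cfg$counts_spec$n_genes
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  spec_builders <- list(counts_spec = count_sim_spec,
                        annotation_spec = annotation_sim_spec,
                        timecourse_spec = timecourse_sim_spec,
                        scene_spec = scene_sim_spec)
  args <- list()
  for (nm in names(raw)) {
    args[[nm]] <- if (nm %in% names(spec_builders)) {
      do.call(spec_builders[[nm]], as.list(raw[[nm]]))
    } else raw[[nm]]
  }
  do.call(pipeline_config, args)
}

#' Validate pipeline inputs without running the pipeline
#'
#' Non-destructive consistency checks: count/metadata agreement, term
#' graph acyclicity, mask integrity (integer labels, background 0,
#' consecutive labels). Failures are reported, not raised.
#'
#' @param config a [pipeline_config()].
#' @return Data frame with columns `stage`, `check`, `ok`, `detail`;
#'   an all-`ok` report has no `FALSE` rows.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rows <- list()
  add <- function(stage, check, ok, detail = "") {
    rows[[length(rows) + 1]] <<- data.frame(stage = stage, check = check,
                                            ok = ok, detail = detail)
  }
  # counts + metadata
  cm <- tryCatch({
    if (!is.null(config$counts_path)) {
      list(counts = read_counts_tsv(config$counts_path),
           metadata = read_metadata_csv(config$metadata_path))
    } else {
      sim <- simulate_counts(config$counts_spec)
      list(counts = sim$counts, metadata = sim$metadata)
    }
  }, error = function(e) e)
  if (inherits(cm, "error")) {
    add("diffexpr", "counts readable", FALSE, conditionMessage(cm))
  } else {
    add("diffexpr", "counts readable", TRUE)
    ok <- tryCatch({
      check_count_matrix(cm$counts); check_metadata(cm$counts, cm$metadata)
      TRUE
    }, error = function(e) conditionMessage(e))
    add("diffexpr", "counts/metadata consistent", isTRUE(ok),
        if (isTRUE(ok)) "" else ok)
  }
  # ontology
  onto <- tryCatch({
    if (!is.null(config$terms_path)) {
      read_ontology_tsv(config$terms_path, config$annotations_path)
    } else simulate_annotations(config$annotation_spec)$ontology
  }, error = function(e) e)
  add("geneset", "term graph acyclic and consistent",
      !inherits(onto, "error"),
      if (inherits(onto, "error")) conditionMessage(onto) else "")
  # masks
  sc <- tryCatch(simulate_aggregate_timeseries(config$scene_spec),
                 error = function(e) e)
  if (inherits(sc, "error")) {
    add("phenotype", "scene realizable", FALSE, conditionMessage(sc))
  } else {
    add("phenotype", "scene realizable", TRUE)
    ok <- all(vapply(sc$masks, function(m) {
      labs <- setdiff(unique(as.integer(m)), 0L)
      all(m >= 0) && setequal(labs, seq_along(labs))
    }, logical(1)))
    add("phenotype", "masks integer with consecutive labels", ok)
  }
  do.call(rbind, rows)
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes differential expression, enrichment, staging and phenotype
#' stages on the configured inputs (synthetic by default) and returns
#' a report bundle: per-stage result tables, a run manifest (seeds,
#' thresholds, package version) and a recovered-vs-planted summary for
#' the synthetic ground truths. Deterministic given the config.
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when set, stage tables are
#'   written there as TSV/CSV and the manifest as JSON.
#' @param stages subset of `c("de", "enrich", "stage", "phenotype")`
#'   to run.
#' @return List of class `pipeline_report` with elements `de`,
#'   `enrich`, `stage`, `phenotype` (those run), `manifest` and
#'   `recovery`.
#' @export
run_pipeline <- function(config, output_dir = NULL,
                         stages = c("de", "enrich", "stage", "phenotype")) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list()
  recovery <- list()

  de <- NULL; sim <- NULL
  if ("de" %in% stages) {
    if (!is.null(config$counts_path)) {
      counts <- read_counts_tsv(config$counts_path)
      meta <- read_metadata_csv(config$metadata_path)
      truth <- NULL
    } else {
      sim <- simulate_counts(config$counts_spec)
      counts <- sim$counts; meta <- sim$metadata; truth <- sim$truth
    }
    sf <- estimate_size_factors(counts)
    flt <- filter_low_expression(counts, sf, config$low_count_threshold)
    disp <- estimate_dispersions(flt$counts, sf, condition_design(meta))
    de <- test_condition_contrast(flt$counts, sf, disp$alpha, meta,
                                  fdr_threshold = config$fdr_threshold)
    up <- de$gene[de$chimera_biased & de$log2FC > 0]
    down <- de$gene[de$chimera_biased & de$log2FC < 0]
    sets <- rbind(
      if (length(up)) summarize_gene_set_fc(de, up, "chimera_up",
                                            seed = derive_seed(config$seed, "fc-up")),
      if (length(down)) summarize_gene_set_fc(de, down, "chimera_down",
                                              seed = derive_seed(config$seed, "fc-down")))
    report$de <- list(result = de, size_factors = sf,
                      filter_report = flt$report, set_summaries = sets)
    if (!is.null(truth)) {
      m <- merge(de[de$tested, c("gene", "log2FC", "chimera_biased")], truth)
      is_de <- m$true_lfc != 0
      recovery$de <- c(
        mean_abs_lfc_error_de = mean(abs(m$log2FC - m$true_lfc)[is_de]),
        fdr_observed = if (any(m$chimera_biased)) {
          mean(m$true_lfc[m$chimera_biased] == 0)
        } else 0)
    }
  }

  if ("enrich" %in% stages) {
    if (!is.null(config$terms_path)) {
      onto <- read_ontology_tsv(config$terms_path, config$annotations_path)
      selected <- de$gene[de$chimera_biased]
      universe <- de$gene[de$tested]
      planted <- NULL
    } else {
      ann <- simulate_annotations(config$annotation_spec)
      onto <- ann$ontology; selected <- ann$selected
      universe <- ann$universe; planted <- ann$enriched_terms
    }
    onto_f <- propagate_annotations(filter_annotations(onto))
    enr <- conditional_go_enrichment(selected, universe, onto_f,
                                     alpha = config$enrich_alpha,
                                     size_window = config$enrich_window)
    perm <- NULL
    if (!is.null(de)) {
      tested <- de[de$tested, ]
      dn <- tested$gene[rank(tested$log2FC) <= 25]   # candidate down set
      perm <- permutation_set_test(dn, de, n_perm = config$n_perm,
                                   direction = "lesser",
                                   seed = derive_seed(config$seed, "perm"))
    }
    report$enrich <- list(enrichment = enr, permutation = perm)
    if (!is.null(planted)) {
      found <- enr$term[enr$significant]
      recovery$enrich <- c(planted_terms = length(planted),
                           recovered = length(intersect(found, planted)))
    }
  }

  if ("stage" %in% stages) {
    tc <- simulate_reference_timecourse(config$timecourse_spec)
    qt <- config$query_times
    pairs <- paste0("p", 1:4)
    qcols <- list()
    qmeta <- NULL
    for (cond in names(qt)) {
      for (p in pairs) {
        s <- derive_seed(config$seed, paste0("query-", cond, "-", p))
        qcols[[paste(cond, p, sep = "_")]] <- tc$query_sampler(qt[[cond]],
                                                               seed = s)
        qmeta <- rbind(qmeta, data.frame(sample = paste(cond, p, sep = "_"),
                                         condition = cond, pair = p))
      }
    }
    qmat <- do.call(cbind, qcols)
    combined <- cbind(tc$counts, qmat)
    sf_all <- estimate_size_factors(combined)
    trans <- rlog_like_transform(combined, sf_all, blind = TRUE)
    prof <- reference_distance_profile(
      trans[, colnames(qmat), drop = FALSE],
      trans[, colnames(tc$counts), drop = FALSE],
      tc$metadata, query_meta = qmeta, genes = tc$timing_genes)
    m_vary <- fit_condition_spline_model(prof, shared_smooth = FALSE)
    m_shared <- fit_condition_spline_model(prof, shared_smooth = TRUE)
    sel <- select_model(m_vary, m_shared)
    best <- if (sel$selected == "varying") m_vary else m_shared
    minima <- locate_minima(best, step = config$fd_step)
    report$stage <- list(profile = prof, model_varying = m_vary,
                         model_shared = m_shared, selection = sel,
                         minima = minima)
    if (nrow(minima)) {
      err <- vapply(seq_len(nrow(minima)), function(i)
        abs(minima$hr[i] - qt[[as.character(minima$condition[i])]]),
        numeric(1))
      recovery$stage <- c(max_minimum_error_hr = max(err))
    }
  }

  if ("phenotype" %in% stages) {
    sc <- simulate_aggregate_timeseries(config$scene_spec)
    particles <- do.call(rbind, lapply(seq_along(sc$masks), function(f)
      measure_particles(sc$masks[[f]], frame = f)))
    params <- select_shape_parameters(
      particles, c("area", "perimeter", "circularity", "aspect_ratio",
                   "solidity"), r_max = config$cor_cap)
    pca <- shape_pca(particles, params)
    events <- track_mask_sequence(sc$masks, config$overlap_frac)
    report$phenotype <- list(particles = particles, parameters = params,
                             pca = pca, events = events)
    truth_parents <- do.call(rbind, lapply(seq_len(nrow(sc$events)), function(i) {
      p <- as.integer(strsplit(sc$events$parents[i], ";")[[1]])
      data.frame(frame_from = sc$events$frame_from[i], label = p,
                 truth = sc$events$type[i])
    }))
    cmp <- merge(events, truth_parents, by = c("frame_from", "label"))
    recovery$phenotype <- c(event_accuracy = mean(cmp$event == cmp$truth))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("dictydev")),
                   seed = config$seed,
                   thresholds = config[c("fdr_threshold", "enrich_alpha",
                                         "enrich_window", "median_window",
                                         "n_perm", "fd_step", "overlap_frac",
                                         "low_count_threshold", "cor_cap")],
                   stages = stages)
  report$manifest <- manifest
  report$recovery <- recovery

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(report$de))
      write_de_tsv(report$de$result, file.path(output_dir, "de_results.tsv"))
    if (!is.null(report$enrich))
      utils::write.table(report$enrich$enrichment,
                         file.path(output_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$stage)) {
      write.csv(report$stage$minima, file.path(output_dir, "staging_minima.csv"),
                row.names = FALSE)
      prof <- report$stage$profile
      write.csv(data.frame(sample = rownames(prof$distance), prof$distance,
                           check.names = FALSE),
                file.path(output_dir, "distance_profile.csv"),
                row.names = FALSE)
      best <- if (report$stage$selection$selected == "varying") {
        report$stage$model_varying
      } else report$stage$model_shared
      jsonlite::write_json(
        list(selected = report$stage$selection$selected,
             delta_aicc = report$stage$selection$delta_aicc,
             p = report$stage$selection$p,
             edf = best$edf, reml = best$reml, aicc = best$aicc,
             condition_coef = as.list(best$condition_coef),
             minima = report$stage$minima),
        file.path(output_dir, "staging_model.json"),
        auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(report$phenotype)) {
      write.csv(report$phenotype$particles,
                file.path(output_dir, "particles.csv"), row.names = FALSE)
      write.csv(report$phenotype$events, file.path(output_dir, "events.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(c(manifest, list(recovery = recovery)),
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "pipeline_report")
}
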