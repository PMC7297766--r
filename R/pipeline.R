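# End-to-end orchestration mirroring the study's order:
# impute -> merge -> symmetry/GPA -> ANCOVA/PCA -> distances -> P-matrices
# -> skewers -> drift test.  Every stage writes its artifact before the next
# starts; the manifest records seeds, parameters, wall times and md5 hashes.

#' Assemble and validate a pipeline configuration
#'
#' @param landmarks,metadata,template_file optional input paths (landmark
#'   file readable by [read_landmarks()], metadata CSV, template JSON).
#'   When `landmarks` is `NULL` the pipeline simulates a demo dataset with
#'   [simulate_shapes()].
#' @param outdir output directory (created).
#' @param n_perm RRPP permutations; `n_vectors` skewers; `t`, `Ne`,
#'   `n_sim`, `n_boot`, `alpha` drift-test parameters; `seed` master seed.
#' @param scale scale to unit centroid size in GPA; `log_traits` log
#'   distances before P-matrix estimation.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(landmarks = NULL, metadata = NULL,
                            template_file = NULL, outdir = tempfile("mdrun"),
                            n_perm = 1000, n_vectors = 1000,
                            t = 370, Ne = 24905, n_sim = 1000, n_boot = 1000,
                            alpha = 0.05, seed = 1L, scale = TRUE,
                            log_traits = FALSE) {
  if (Ne <= 0) stop("Ne must be positive")
  if (t <= 0) stop("t must be positive")
  if (n_perm < 10 || n_vectors < 10) stop("n_perm and n_vectors too small")
  if (n_sim < 100 || n_boot < 100) stop("n_sim and n_boot must be >= 100")
  for (pth in c(landmarks, metadata, template_file))
    if (!is.null(pth) && !file.exists(pth)) stop("missing input path: ", pth)
  structure(list(landmarks = landmarks, metadata = metadata,
                 template_file = template_file, outdir = outdir,
                 n_perm = n_perm, n_vectors = n_vectors, t = t, Ne = Ne,
                 n_sim = n_sim, n_boot = n_boot, alpha = alpha,
                 seed = as.integer(seed), scale = scale,
                 log_traits = log_traits),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

write_aligned_csv <- function(al, path) {
  n <- dim(al$shapes)[1]; p <- dim(al$shapes)[2]
  df <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(specimen_id = al$meta$specimen_id[i],
               replicate = al$meta$replicate[i],
               landmark = seq_len(p),
               x = al$shapes[i, , 1], y = al$shapes[i, , 2],
               z = al$shapes[i, , 3],
               centroid_size = al$centroid_sizes[i])))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()] or path to a JSON config.
#' @return list with every stage result plus `manifest` (also written to
#'   `manifest.json` in `outdir`).  Deterministic given the master seed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list(); timings <- c(); results <- list()
  stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e) {
      manifest <- list(status = "failed", failed_stage = name,
                       error = conditionMessage(e), seed = config$seed,
                       artifacts = artifacts, timings_sec = as.list(timings))
      jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  add_artifact <- function(label, path) artifacts[[label]] <<- basename(path)

  ds <- stage("input", function() {
    if (is.null(config$landmarks)) {
      tpl <- make_template(n_pairs = 19, n_midline = 5, seed = 43L)
      base <- attr(tpl, "base_shape")
      set.seed(config$seed)
      cfg <- synthetic_shape_config(
        tpl,
        allometry = matrix(stats::rnorm(nrow(base) * 3, 0, 0.004), ncol = 3),
        period_effect = matrix(stats::rnorm(nrow(base) * 3, 0, 0.006), ncol = 3),
        sex_effect = matrix(stats::rnorm(nrow(base) * 3, 0, 0.002), ncol = 3),
        seed = config$seed)
      simulate_shapes(cfg)
    } else {
      tpl <- if (!is.null(config$template_file))
        template_from_json(config$template_file) else cranium_template()
      read_landmarks(config$landmarks, template = tpl,
                     metadata = config$metadata)
    }
  })
  lmpath <- file.path(config$outdir, "landmarks.csv")
  write_landmarks(ds, lmpath, format = "csv"); add_artifact("landmarks", lmpath)

  aligned <- stage("align", function() {
    ds2 <- impute_missing(ds)
    if (nrow(ds2$template$paired) > 0)
      symmetric_decomposition(ds2, scale = config$scale)$symmetric
    else gpa_align(ds2, scale = config$scale)
  })
  alpath <- file.path(config$outdir, "aligned.csv")
  write_aligned_csv(aligned, alpath); add_artifact("aligned", alpath)
  jsonlite::write_json(list(passes = length(aligned$iterations),
                            residual_log = aligned$iterations,
                            component = aligned$component),
                       file.path(config$outdir, "alignment_report.json"),
                       auto_unbox = TRUE, digits = NA)
  add_artifact("alignment_report", "alignment_report.json")

  prim <- aligned$meta$replicate == 0
  Y <- flatten_shapes(aligned$shapes[prim, , , drop = FALSE])
  covars <- data.frame(log_size = log(aligned$centroid_sizes[prim]),
                       period = factor(aligned$meta$period[prim]),
                       sex = factor(aligned$meta$sex[prim]))
  anova_res <- stage("anova", function() rrpp_lm(
    Y, model_spec(c("log_size", "period", "sex", "log_size:period",
                    "log_size:sex", "period:sex", "log_size:period:sex"),
                  n_perm = config$n_perm, seed = config$seed), covars))
  anpath <- file.path(config$outdir, "shape_anova.csv")
  utils::write.csv(anova_res$table, anpath, row.names = FALSE)
  add_artifact("shape_anova", anpath)

  size_res <- stage("size_anova", function() rrpp_lm(
    covars$log_size,
    model_spec(c("period", "sex", "period:sex"),
               n_perm = config$n_perm, seed = config$seed), covars))
  szpath <- file.path(config$outdir, "size_anova.csv")
  utils::write.csv(size_res$table, szpath, row.names = FALSE)
  add_artifact("size_anova", szpath)

  pca <- stage("pca", function() shape_pca(
    aligned$shapes[prim, , , drop = FALSE]))
  pcpath <- file.path(config$outdir, "pca_scores.csv")
  utils::write.csv(data.frame(specimen_id = aligned$meta$specimen_id[prim],
                              pca$scores), pcpath, row.names = FALSE)
  add_artifact("pca_scores", pcpath)

  traits <- stage("traits", function() interlandmark_distances(
    impute_missing(ds), log = config$log_traits))
  trpath <- file.path(config$outdir, "traits.csv")
  utils::write.csv(data.frame(specimen_id = traits$specimens,
                              population = traits$population, traits$values),
                   trpath, row.names = FALSE)
  add_artifact("traits", trpath)

  P1 <- stage("pmatrix", function() p_matrix(traits, "1890s"))
  P2 <- p_matrix(traits, "2010s")
  pmpath <- file.path(config$outdir, "p_matrices.csv")
  utils::write.csv(rbind(data.frame(population = "1890s", trait = P1$labels, P1$cov),
                         data.frame(population = "2010s", trait = P2$labels, P2$cov)),
                   pmpath, row.names = FALSE)
  add_artifact("p_matrices", pmpath)

  skew <- stage("skewers", function() random_skewers(
    P1, P2, n_vectors = config$n_vectors, seed = config$seed))
  skpath <- file.path(config$outdir, "skewers.json")
  jsonlite::write_json(list(correlation = skew$correlation, p = skew$p,
                            n_vectors = skew$n_vectors, seed = config$seed),
                       skpath, auto_unbox = TRUE, digits = NA)
  add_artifact("skewers", skpath)

  drift <- stage("drift", function() {
    rows1 <- traits$population == "1890s"; rows2 <- traits$population == "2010s"
    drift_divergence_test(traits$values[rows1, , drop = FALSE],
                          traits$values[rows2, , drop = FALSE], P1,
                          drift_params(config$t, config$Ne, config$n_sim,
                                       config$n_boot, seed = config$seed,
                                       alpha = config$alpha))
  })
  drpath <- file.path(config$outdir, "drift_test.json")
  jsonlite::write_json(list(delta_z = drift$delta_z,
                            observed_norm = drift$observed_norm,
                            observed_ci = drift$observed_ci,
                            drift_ci = drift$drift_ci,
                            verdict = drift$verdict,
                            params = drift$params[c("t", "Ne", "n_sim",
                                                    "n_boot", "alpha",
                                                    "correct_sampling")]),
                       drpath, auto_unbox = TRUE, digits = NA)
  add_artifact("drift_test", drpath)

  files <- file.path(config$outdir, unlist(artifacts))
  manifest <- list(status = "ok", package = "morphdrift",
                   version = as.character(utils::packageVersion("morphdrift")),
                   seed = config$seed,
                   config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
                   artifacts = artifacts,
                   md5 = as.list(tools::md5sum(files)),
                   timings_sec = as.list(timings))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dataset = ds, aligned = aligned, anova = anova_res,
                 size_anova = size_res, pca = pca, traits = traits,
                 P1 = P1, P2 = P2, skewers = skew, drift = drift,
                 manifest = manifest))
}

#' Serialize / deserialize a template as JSON
#' @param template a `landmark_template`.
#' @param path JSON file.
#' @return `template_to_json` returns `path`; `template_from_json` a
#'   `landmark_template`.
#' @export
template_to_json <- function(template, path) {
  jsonlite::write_json(list(
    landmark_names = template$landmark_names, dim = template$dim,
    paired = as.data.frame(template$paired), midline = template$midline,
    views = as.list(template$views), distance_defs = template$distance_defs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname template_to_json
#' @export
template_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dd <- as.data.frame(x$distance_defs)
  if (!nrow(dd)) dd <- NULL
  landmark_template(x$landmark_names,
                    paired = if (length(x$paired)) as.matrix(x$paired) else NULL,
                    midline = x$midline,
                    views = unlist(x$views), distance_defs = dd,
                    dim = x$dim)
}
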