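pipeline_stages <- c("simulate", "synth", "preprocess", "train", "coordinate",
                     "energetics", "stats")

# deterministic per-stage seed fan-out from the global seed:
# seed_k = (global * 131 + 17 * stage_index) mod (2^31 - 1)
stage_seed <- function(global_seed, stage) {
  k <- match(stage, pipeline_stages)
  as.integer((as.numeric(global_seed) * 131 + 17 * k) %% (2^31 - 1))
}

preset_defaults <- function(preset) {
  switch(preset,
    full = list(steps = 5e7, save_every = 500L, equil_steps = 1e5,
                 epochs = 1000L, n_per_type = 5000L),
    desk = list(steps = 5e5, save_every = 250L, equil_steps = 1e5,
                epochs = 150L, n_per_type = 800L),
    stop("unknown scale preset '", preset, "' (use 'full' or 'desk')"))
}

#' Validate and complete a pipeline configuration
#'
#' Reads a YAML configuration, fills stage defaults according to the scale
#' preset, and checks cross-stage consistency (the nm binarization cutoff
#' should equal `nm_per_sigma * contact_cutoff`).
#'
#' @param path YAML file. Recognized top-level fields: `seed` (required),
#'   `preset` (`"full"` or `"desk"`, default `"desk"`), `out_dir`, and the
#'   optional blocks `simulate` (`steps`, `save_every`, `equil_steps`),
#'   `synth` (fields of [synth_config()]), `preprocess` (`cutoff_nm`),
#'   `train` (`epochs`, `latent_dim_coord`, `latent_dim_prob`).
#' @return a validated `run_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config is missing required field 'seed'")
  preset <- raw$preset %||% "desk"
  def <- preset_defaults(preset)
  cfg <- list(
    seed = as.integer(raw$seed),
    preset = preset,
    out_dir = raw$out_dir %||% "tadfold_run",
    simulate = list(
      steps = raw$simulate$steps %||% def$steps,
      save_every = raw$simulate$save_every %||% def$save_every,
      equil_steps = raw$simulate$equil_steps %||% def$equil_steps),
    synth = list(
      nm_per_sigma = raw$synth$nm_per_sigma %||% 150,
      noise_sd = raw$synth$noise_sd %||% 30,
      missing_prob = raw$synth$missing_prob %||% 0.1,
      n_per_type = raw$synth$n_per_type %||% def$n_per_type),
    preprocess = list(cutoff_nm = raw$preprocess$cutoff_nm %||% 450),
    train = list(
      epochs = raw$train$epochs %||% def$epochs,
      batch_size = raw$train$batch_size %||% 500L,
      learning_rate = raw$train$learning_rate %||% 0.001,
      latent_dim_coord = raw$train$latent_dim_coord %||% 2L,
      latent_dim_prob = raw$train$latent_dim_prob %||% 25L)
  )
  params <- polymer_params()
  expected <- cfg$synth$nm_per_sigma * params$contact_cutoff
  if (abs(cfg$preprocess$cutoff_nm - expected) > 1e-6)
    warning("binarization cutoff ", cfg$preprocess$cutoff_nm,
            " nm does not equal nm_per_sigma * contact_cutoff = ", expected,
            " nm; simulated and imaging contacts will not be commensurable")
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Executes the requested stages in order -- polymer simulation, synthetic
#' imaging data, preprocessing, VAE training, folding coordinate,
#' energetics, structure statistics -- writing each stage's artifacts under
#' `cfg$out_dir` plus a JSON manifest with parameters and file hashes. A
#' stage whose upstream artifact is absent raises an error naming the stage
#' to run first.
#'
#' @param cfg a [validate_config()] result.
#' @param stages character subset of
#'   `c("simulate","synth","preprocess","train","coordinate","energetics","stats")`.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(cfg, stages = pipeline_stages) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(out, f)
  need <- function(file, producer) {
    if (!file.exists(art(file)))
      stop("missing artifact '", file, "'; run stage '", producer, "' first")
  }
  manifest <- list(config = unclass(cfg), stages = list())
  params <- polymer_params()

  if ("simulate" %in% stages) {
    s <- stage_seed(cfg$seed, "simulate")
    ref <- run_langevin(params, cfg$simulate$steps, cfg$simulate$save_every,
                        seed = s, chromatin_like = FALSE,
                        equil_steps = cfg$simulate$equil_steps)
    chrom <- run_langevin(params, cfg$simulate$steps, cfg$simulate$save_every,
                          seed = s + 1L, chromatin_like = TRUE,
                          equil_steps = cfg$simulate$equil_steps)
    write_trajectory(ref, art("ref_traj.xyz"))
    write_trajectory(chrom, art("chrom_traj.xyz"))
    manifest$stages$simulate <- list(frames = length(ref), seed = s)
  }

  if ("synth" %in% stages) {
    need("ref_traj.xyz", "simulate"); need("chrom_traj.xyz", "simulate")
    ref <- read_trajectory(art("ref_traj.xyz"))
    chrom <- read_trajectory(art("chrom_traj.xyz"))
    scfg <- synth_config(nm_per_sigma = cfg$synth$nm_per_sigma,
                         noise_sd = cfg$synth$noise_sd,
                         missing_prob = cfg$synth$missing_prob,
                         n_per_type = cfg$synth$n_per_type,
                         seed = stage_seed(cfg$seed, "synth"))
    cells <- generate_dataset(ref, chrom, scfg)
    write_traces(cells, art("traces.tsv"))
    manifest$stages$synth <- list(n_cells = length(cells))
  }

  if ("preprocess" %in% stages) {
    need("traces.tsv", "synth")
    cells <- read_traces(art("traces.tsv"))
    qd <- preprocess_traces(cells, cutoff_nm = cfg$preprocess$cutoff_nm,
                            seed = stage_seed(cfg$seed, "preprocess"))
    utils::write.table(cbind(cell_id = qd$cell_ids, label = qd$labels,
                             as.data.frame(qd$vectors)),
                       art("qdata.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$stages$preprocess <- list(n_bins = qd$n_bins)
  }

  if ("train" %in% stages) {
    need("qdata.tsv", "preprocess")
    qd <- read_qdata(art("qdata.tsv"))
    tc <- train_config(epochs = cfg$train$epochs,
                       batch_size = cfg$train$batch_size,
                       learning_rate = cfg$train$learning_rate,
                       seed = stage_seed(cfg$seed, "train"))
    model <- train_vae(qd$vectors,
                       vae_architecture(ncol(qd$vectors),
                                        latent_dim = cfg$train$latent_dim_coord),
                       tc)
    saveRDS(model, art("model_coord.rds"))
    for (lb in unique(qd$labels)) {
      m <- train_vae(qd$vectors[qd$labels == lb, , drop = FALSE],
                     vae_architecture(ncol(qd$vectors),
                                      latent_dim = cfg$train$latent_dim_prob),
                     tc)
      saveRDS(m, art(paste0("model_prob_", lb, ".rds")))
    }
    manifest$stages$train <- list(final_elbo = utils::tail(model$elbo, 1))
  }

  if ("coordinate" %in% stages) {
    need("model_coord.rds", "train"); need("qdata.tsv", "preprocess")
    qd <- read_qdata(art("qdata.tsv"))
    model <- readRDS(art("model_coord.rds"))
    emb <- encode(model, qd$vectors)$mean
    labs <- unique(qd$labels)
    sep <- fit_separator(emb[qd$labels == labs[1], , drop = FALSE],
                         emb[qd$labels == labs[2], , drop = FALSE])
    coords <- coordinate_value(sep, emb)
    utils::write.table(
      data.frame(cell_id = qd$cell_ids, label = qd$labels,
                 z1 = emb[, 1], z2 = emb[, 2], coordinate = coords),
      art("coords.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$coordinate <- list(
      misclassification = misclassification_rate(
        sep, emb[qd$labels == labs[1], , drop = FALSE],
        emb[qd$labels == labs[2], , drop = FALSE]))
  }

  if ("energetics" %in% stages) {
    need("coords.tsv", "coordinate"); need("qdata.tsv", "preprocess")
    qd <- read_qdata(art("qdata.tsv"))
    co <- utils::read.delim(art("coords.tsv"))
    labs <- unique(qd$labels)
    m_a <- readRDS(art(paste0("model_prob_", labs[1], ".rds")))
    m_b <- readRDS(art(paste0("model_prob_", labs[2], ".rds")))
    s <- stage_seed(cfg$seed, "energetics")
    lp <- numeric(nrow(qd$vectors))
    for (lb in labs) {
      sel <- qd$labels == lb
      mdl <- if (lb == labs[1]) m_a else m_b
      lp[sel] <- estimate_log_prob(mdl, qd$vectors[sel, , drop = FALSE],
                                   seed = s)
    }
    write_profile(profile_along_coordinate(-lp, co$coordinate),
                  art("free_energy_profile.tsv"))
    manifest$stages$energetics <- list(mean_free_energy = mean(-lp))
  }

  if ("stats" %in% stages) {
    need("traces.tsv", "synth")
    cells <- read_traces(art("traces.tsv"))
    labs <- vapply(cells, function(tr) tr$label, character(1))
    for (lb in unique(labs)) {
      mp <- mean_distance_map(cells[labs == lb])
      utils::write.table(round(mp, 3), art(paste0("mean_dist_", lb, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      prof <- boundary_score_profile(mp)
      utils::write.table(data.frame(bin = seq_along(prof), score = prof),
                         art(paste0("boundary_score_", lb, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$stats <- list(labels = unique(labs))
  }

  files <- list.files(out, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$artifacts <- lapply(stats::setNames(files, basename(files)),
                               function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back an XYZ-style trajectory written by [write_trajectory()]
#'
#' @param path trajectory file.
#' @return list of n x 3 conformation matrices.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  starts <- grep("^# frame", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    block <- lines[(starts[k] + 1L):ends[k]]
    m <- do.call(rbind, lapply(strsplit(block, " ", fixed = TRUE),
                               function(p) as.numeric(p[2:4])))
    m
  })
}

read_qdata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  list(vectors = as.matrix(df[, -(1:2)]),
       labels = df$label, cell_ids = df$cell_id)
}
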