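new_cell_trace <- function(cell_id, positions, label = "unknown") {
  stopifnot(is.matrix(positions), ncol(positions) == 3L)
  missing_mask <- !stats::complete.cases(positions)
  positions[missing_mask, ] <- NA_real_
  structure(list(cell_id = as.character(cell_id), positions = positions,
                 missing_mask = missing_mask, label = as.character(label)),
            class = "cell_trace")
}

#' @export
print.cell_trace <- function(x, ...) {
  cat("<cell_trace> ", x$cell_id, " (", x$label, "): ",
      nrow(x$positions), " probes, ", sum(x$missing_mask), " missing\n",
      sep = "")
  invisible(x)
}

#' Configuration of the synthetic imaging-data generator
#'
#' Describes how simulated polymer conformations are turned into
#' imaging-like traces of two cell populations. WT-like cells are drawn from
#' the chromatin-like (two-domain) ensemble; depleted-like cells are a
#' mixture dominated by the unstructured reference ensemble with a minority
#' of domain-forming frames, emulating the observation that a substantial
#' fraction of cohesin-depleted cells still shows TAD-like structures.
#'
#' @param nm_per_sigma physical length of one simulation length unit (nm);
#'   the default 150 maps the 3 sigma simulation contact cutoff exactly onto
#'   the 450 nm imaging cutoff.
#' @param noise_sd isotropic Gaussian localization noise per axis (nm).
#' @param missing_prob probability that a probe is missing (independently
#'   per probe).
#' @param n_per_type number of cells generated per population.
#' @param mixture_weights named fractions (`reference`, `chromatin`) of
#'   depleted-like cells drawn from each ensemble; must sum to 1.
#' @param seed integer RNG seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(nm_per_sigma = 150, noise_sd = 30, missing_prob = 0.1,
                         n_per_type = 1000L,
                         mixture_weights = c(reference = 0.85, chromatin = 0.15),
                         seed = 1L) {
  stopifnot(nm_per_sigma > 0, noise_sd >= 0,
            missing_prob >= 0, missing_prob <= 1, n_per_type >= 1,
            abs(sum(mixture_weights) - 1) < 1e-9,
            all(c("reference", "chromatin") %in% names(mixture_weights)))
  structure(list(nm_per_sigma = nm_per_sigma, noise_sd = noise_sd,
                 missing_prob = missing_prob,
                 n_per_type = as.integer(n_per_type),
                 mixture_weights = mixture_weights, seed = as.integer(seed)),
            class = "synth_config")
}

sample_frames <- function(n_frames, n_cells) {
  if (n_cells > n_frames) {
    warning("requested ", n_cells, " cells from ", n_frames,
            " frames; sampling with replacement")
    sample.int(n_frames, n_cells, replace = TRUE)
  } else {
    sample.int(n_frames, n_cells)
  }
}

#' Generate an imaging-like two-population trace dataset
#'
#' @param ref_traj list of reference-ensemble conformations (sigma units).
#' @param chrom_traj list of chromatin-like-ensemble conformations.
#' @param cfg a [synth_config()].
#' @return list of `cell_trace` objects with labels `"WT"` and `"depleted"`.
#' @export
generate_dataset <- function(ref_traj, chrom_traj, cfg = synth_config()) {
  stopifnot(length(ref_traj) >= 1L, length(chrom_traj) >= 1L)
  set.seed(cfg$seed)
  n <- cfg$n_per_type

  make_cells <- function(frames, prefix, label) {
    lapply(seq_along(frames), function(k) {
      pos <- frames[[k]] * cfg$nm_per_sigma
      if (cfg$noise_sd > 0)
        pos <- pos + matrix(stats::rnorm(length(pos), sd = cfg$noise_sd),
                            nrow(pos), 3L)
      if (cfg$missing_prob > 0) {
        miss <- stats::runif(nrow(pos)) < cfg$missing_prob
        pos[miss, ] <- NA_real_
      }
      new_cell_trace(sprintf("%s_%05d", prefix, k), pos, label)
    })
  }

  wt_frames <- chrom_traj[sample_frames(length(chrom_traj), n)]
  wt <- make_cells(wt_frames, "WT", "WT")

  src <- sample(c("reference", "chromatin"), n, replace = TRUE,
                prob = cfg$mixture_weights[c("reference", "chromatin")])
  n_ref <- sum(src == "reference")
  dep_frames <- vector("list", n)
  dep_frames[src == "reference"] <- ref_traj[sample_frames(length(ref_traj), n_ref)]
  dep_frames[src == "chromatin"] <-
    chrom_traj[sample_frames(length(chrom_traj), n - n_ref)]
  dep <- make_cells(dep_frames, "DEP", "depleted")

  c(wt, dep)
}

#' Write cell traces to a TSV file
#'
#' One row per probe with columns `cell_id`, `bin_index` (0-based), `x_nm`,
#' `y_nm`, `z_nm`, `label`; missing probes have empty coordinate fields.
#'
#' @param cells list of `cell_trace` objects.
#' @param path output file path.
#' @export
write_traces <- function(cells, path) {
  rows <- lapply(cells, function(tr) {
    data.frame(cell_id = tr$cell_id,
               bin_index = seq_len(nrow(tr$positions)) - 1L,
               x_nm = tr$positions[, 1], y_nm = tr$positions[, 2],
               z_nm = tr$positions[, 3], label = tr$label)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read cell traces from a TSV file
#'
#' Inverse of [write_traces()]; `read_traces(write_traces(x))` reproduces
#' the dataset field by field.
#'
#' @param path TSV file as written by [write_traces()].
#' @return list of `cell_trace` objects (empty, with a warning, for an
#'   empty file).
#' @export
read_traces <- function(path) {
  lines <- readLines(path)
  if (length(lines) <= 1L) {
    warning("trace file ", path, " contains no data rows")
    return(list())
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("cell_id", "bin_index", "x_nm", "y_nm", "z_nm", "label")
  if (!all(need %in% header))
    stop("trace file missing column(s): ",
         paste(setdiff(need, header), collapse = ", "))
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncol_exp <- length(header)
  num <- function(x, line, col) {
    x[x == ""] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at line ", line[bad[1]])
    v
  }
  m <- vapply(parts, function(p) {
    length(p) <- ncol_exp
    p
  }, character(ncol_exp))
  m <- t(m)
  colnames(m) <- header
  line_no <- seq_len(nrow(m)) + 1L
  df <- data.frame(cell_id = m[, "cell_id"],
                   bin_index = num(m[, "bin_index"], line_no, "bin_index"),
                   x_nm = num(m[, "x_nm"], line_no, "x_nm"),
                   y_nm = num(m[, "y_nm"], line_no, "y_nm"),
                   z_nm = num(m[, "z_nm"], line_no, "z_nm"),
                   label = m[, "label"], stringsAsFactors = FALSE)
  if (any(is.na(df$cell_id) | df$cell_id == ""))
    stop("missing cell_id at line ", line_no[which(df$cell_id == "")[1]])
  lapply(split(df, factor(df$cell_id, levels = unique(df$cell_id))),
         function(d) {
           d <- d[order(d$bin_index), ]
           new_cell_trace(d$cell_id[1],
                          as.matrix(d[, c("x_nm", "y_nm", "z_nm")]),
                          d$label[1])
         }) |> unname()
}
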