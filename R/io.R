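#' Read a regional BOLD matrix from delimited text
#'
#' One row per region. An optional leading column may carry region labels and
#' an optional header row is skipped; both are auto-detected (non-numeric
#' fields). The delimiter is auto-detected among comma, tab and whitespace.
#'
#' @param file Path to a CSV/TSV file.
#' @param sampling_interval TR in seconds (default 1.5).
#' @return A [bold_matrix()].
#' @export
read_bold_matrix <- function(file, sampling_interval = 1.5) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (grepl(",", lines[1])) "," else if (grepl("\t", lines[1])) "\t"
         else "[ \t]+"
  rows <- strsplit(lines, sep)
  is_num <- function(x) !anyNA(suppressWarnings(as.numeric(x)))
  if (!is_num(rows[[1]][-1])) rows <- rows[-1]          # header row
  labels <- NULL
  if (!is_num(vapply(rows, `[[`, character(1), 1))) {    # label column
    labels <- vapply(rows, `[[`, character(1), 1)
    rows <- lapply(rows, `[`, -1)
  }
  vals <- do.call(rbind, lapply(rows, as.numeric))
  bold_matrix(vals, region_labels = labels,
              sampling_interval = sampling_interval)
}

#' Write / read a topology as a plain edge list
#'
#' Two whitespace-separated 1-based node indices per line, preceded by a
#' `# n_nodes=<n>` header comment.
#'
#' @param top A [topology()].
#' @param file Path.
#' @return `write_edge_list` returns `file` invisibly; `read_edge_list`
#'   returns a [topology()].
#' @export
write_edge_list <- function(top, file) {
  stopifnot(inherits(top, "topology"))
  lines <- c(sprintf("# n_nodes=%d", top$n_nodes),
             sprintf("%d %d", top$edges[, 1], top$edges[, 2]))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#\\s*n_nodes=", lines, value = TRUE)
  if (length(hdr) == 0) stop_input("edge list lacks a '# n_nodes=' header")
  n <- as.integer(sub("^#\\s*n_nodes=\\s*", "", hdr[1]))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  edges <- if (length(body)) {
    do.call(rbind, lapply(strsplit(trimws(body), "[ \t]+"),
                          function(x) as.integer(x[1:2])))
  } else {
    matrix(integer(0), 0, 2)
  }
  topology(n, edges, meta = list(generator = "file", path = file))
}

#' Write / read a spike raster as an event list
#'
#' Text format: header comments `# channels=`, `# timesteps=`, `# dt=`
#' followed by one `channel<TAB>timestep` line per spike (1-based indices).
#'
#' @param r A [spike_raster()].
#' @param file Path.
#' @return `write_raster_events` returns `file` invisibly;
#'   `read_raster_events` returns a [spike_raster()].
#' @export
write_raster_events <- function(r, file) {
  stopifnot(inherits(r, "spike_raster"))
  ev <- which(unclass(r) == 1L, arr.ind = TRUE)
  ev <- ev[order(ev[, 2], ev[, 1]), , drop = FALSE]
  lines <- c(sprintf("# channels=%d", nrow(r)),
             sprintf("# timesteps=%d", ncol(r)),
             sprintf("# dt=%.12g", attr(r, "dt")),
             sprintf("%d\t%d", ev[, 1], ev[, 2]))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_raster_events
#' @export
read_raster_events <- function(file) {
  lines <- readLines(file)
  get_hdr <- function(key) {
    h <- grep(paste0("^#\\s*", key, "="), lines, value = TRUE)
    if (length(h) == 0) stop_input("raster file lacks '# ", key, "=' header")
    as.numeric(sub(paste0("^#\\s*", key, "=\\s*"), "", h[1]))
  }
  ch <- as.integer(get_hdr("channels"))
  ts <- as.integer(get_hdr("timesteps"))
  dt <- get_hdr("dt")
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- matrix(0L, ch, ts)
  if (length(body)) {
    ev <- do.call(rbind, lapply(strsplit(trimws(body), "[ \t]+"),
                                function(x) as.integer(x[1:2])))
    m[ev] <- 1L
  }
  spike_raster(m, dt)
}

#' Write / read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE support for the package's audio interchange; samples are
#' clipped to \[-1, 1\] and quantised to 16 bits.
#'
#' @param w A [waveform()].
#' @param file Path.
#' @return `write_wav` returns `file` invisibly; `read_wav` returns a
#'   [waveform()].
#' @export
write_wav <- function(w, file) {
  stopifnot(inherits(w, "waveform"))
  fs <- as.integer(w$sample_rate)
  pcm <- as.integer(round(pmin(pmax(w$samples, -1), 1) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(file, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")       # PCM
  writeBin(1L, con, size = 2, endian = "little")       # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")       # block align
  writeBin(16L, con, size = 2, endian = "little")      # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(file)
}

#' @rdname write_wav
#' @export
read_wav <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop_input("not a RIFF/WAVE file")
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop_input("no data chunk found")
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) {
        stop_input("only mono PCM WAV is supported")
      }
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = size - 8))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = size / 2, size = 2,
                     endian = "little", signed = TRUE)
      if (is.null(sample_rate)) stop_input("data chunk precedes fmt chunk")
      return(waveform(pcm / 32767, sample_rate))
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
}

#' Save / load a trained readout model as JSON
#'
#' Serialises the weights, templates, input map, seeds and all run
#' parameters, plus the initial reservoir synapse table, so that
#' classification is exactly reproducible after a round trip.
#'
#' @param model A `readout_model`.
#' @param file Path.
#' @return `write_readout_model` returns `file` invisibly;
#'   `read_readout_model` returns a `readout_model`.
#' @export
write_readout_model <- function(model, file) {
  stopifnot(inherits(model, "readout_model"))
  res <- model$reservoir
  payload <- list(
    weights = unname(model$weights),
    classes = model$classes,
    templates = model$templates[model$classes],
    input_map = model$input_map,
    params = model$params,
    reservoir = list(
      n_nodes = res$topology$n_nodes,
      edges = unname(res$topology$edges),
      is_excitatory = res$is_excitatory,
      seed = res$seed,
      nparams = unclass(res$nparams),
      sparams = unclass(res$sparams),
      synapses = as.list(res$synapses[c("pre", "post", "kind", "g",
                                        "delay", "r_g")])
    )
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_readout_model
#' @export
read_readout_model <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  top <- topology(p$reservoir$n_nodes, p$reservoir$edges)
  nparams <- do.call(neuron_params, p$reservoir$nparams)
  sparams <- do.call(synapse_params, p$reservoir$sparams)
  syn <- tibble::as_tibble(p$reservoir$synapses)
  syn$last_pre <- NA_real_
  syn$last_post <- NA_real_
  reservoir <- structure(list(
    v = rep(nparams$v_rest, top$n_nodes),
    ref = rep(0, top$n_nodes),
    synapses = syn,
    is_excitatory = p$reservoir$is_excitatory,
    clock = 0, nparams = nparams, sparams = sparams,
    seed = p$reservoir$seed, topology = top
  ), class = "reservoir_state")
  w <- matrix(p$weights, ncol = length(p$classes),
              dimnames = list(NULL, p$classes))
  templates <- p$templates
  names(templates) <- p$classes
  structure(list(weights = w, templates = templates, classes = p$classes,
                 input_map = p$input_map, reservoir = reservoir,
                 params = p$params, history = tibble::tibble()),
            class = "readout_model")
}

#' Read a JSON run configuration
#'
#' Expects optional `neuron`, `synapse` and `simulation` blocks overriding
#' the package defaults.
#'
#' @param file Path to a JSON file.
#' @return List with `nparams`, `sparams`, `simulation`.
#' @export
read_run_config <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  list(
    nparams = do.call(neuron_params, as.list(cfg$neuron)),
    sparams = do.call(synapse_params, as.list(cfg$synapse)),
    simulation = as.list(cfg$simulation)
  )
}
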