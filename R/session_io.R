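#' @title Session serialization
#'
#' @description Evolution sessions round-trip through plain-text artifacts:
#' JSON for configuration, generator recipes and the neuron model, CSV for
#' latents, scores, optimizer traces and spike records, and a JSON manifest
#' carrying MD5 checksums of every file. Images are not stored: generators
#' are deterministic, so stimuli are reconstructed exactly by re-rendering
#' the stored latents.
#'
#' @name session_io
NULL

fmt_num <- function(x) sprintf("%.17g", x)

write_num_csv <- function(df, path) {
  for (cn in names(df)) {
    if (is.double(df[[cn]])) df[[cn]] <- fmt_num(df[[cn]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

serialize_neuron <- function(neuron) {
  list(template = list(values = as.numeric(neuron$template),
                       dim = dim(neuron$template)),
       locus = neuron$locus, tuning_width = neuron$tuning_width,
       baseline_rate = neuron$baseline_rate, peak_rate = neuron$peak_rate,
       image_size = neuron$image_size,
       kernels = lapply(neuron$kernels, function(k) {
         out <- list(latency = k$latency, width = k$width, gain = k$gain)
         if (!is.null(k$tuning_width)) out$tuning_width <- k$tuning_width
         if (!is.null(k$template)) {
           out$template <- list(values = as.numeric(k$template),
                                dim = dim(k$template))
         }
         out
       }))
}

deserialize_neuron <- function(sp) {
  kern <- lapply(sp$kernels, function(k) {
    out <- list(latency = k$latency, width = k$width, gain = k$gain)
    if (!is.null(k$tuning_width)) out$tuning_width <- k$tuning_width
    if (!is.null(k$template)) {
      out$template <- array(k$template$values, dim = k$template$dim)
    }
    out
  })
  neuron_model(template = array(sp$template$values, dim = sp$template$dim),
               locus = sp$locus, tuning_width = sp$tuning_width,
               baseline_rate = sp$baseline_rate, peak_rate = sp$peak_rate,
               kernels = kern, image_size = sp$image_size)
}

#' Rebuild the two generators of a saved session
#'
#' @param session an `evolution_session`.
#' @return List with generators `a` and `b` reconstructed from their
#'   recipes.
#' @export
session_generators <- function(session) {
  build <- function(recipe) {
    fun <- get(recipe$fun, envir = asNamespace("evomanifold"))
    do.call(fun, recipe$args)
  }
  list(a = build(session$generators$a), b = build(session$generators$b))
}

#' Save an evolution session to a directory
#'
#' @param session an `evolution_session`.
#' @param outdir writable output directory (created if absent).
#' @return The manifest (invisibly); written as `manifest.json` alongside
#'   the session files.
#' @export
save_session <- function(session, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- character()
  put <- function(name) files <<- c(files, name)

  meta <- list(config = session$config, master_seed = session$master_seed,
               generators = session$generators,
               neuron = serialize_neuron(session$neuron),
               final_mean = session$final_mean,
               ref_ids = session$ref$ids,
               log = as.list(session$log))
  jsonlite::write_json(meta, file.path(outdir, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  put("session.json")

  for (th in c("a", "b")) {
    tr <- session$threads[[th]]
    lat <- do.call(rbind, lapply(seq_along(tr$latents), function(b) {
      data.frame(block = b, candidate = seq_len(nrow(tr$latents[[b]])),
                 tr$latents[[b]], check.names = FALSE)
    }))
    names(lat)[-(1:2)] <- sprintf("z%03d", seq_len(ncol(lat) - 2))
    write_num_csv(lat, file.path(outdir, sprintf("thread_%s_latents.csv", th)))
    put(sprintf("thread_%s_latents.csv", th))
    sc <- do.call(rbind, lapply(seq_along(tr$scores), function(b) {
      data.frame(block = b, image_id = tr$image_ids[[b]],
                 score_spk_s = tr$scores[[b]])
    }))
    write_num_csv(sc, file.path(outdir, sprintf("thread_%s_scores.csv", th)))
    put(sprintf("thread_%s_scores.csv", th))
    trace <- data.frame(generation = seq_along(tr$trace$sigma),
                        sigma = tr$trace$sigma, tr$trace$means,
                        check.names = FALSE)
    names(trace)[-(1:2)] <- sprintf("m%03d", seq_len(ncol(trace) - 2))
    write_num_csv(trace, file.path(outdir, sprintf("thread_%s_trace.csv", th)))
    put(sprintf("thread_%s_trace.csv", th))
  }

  for (nm in c("a", "b")) {
    rl <- session$ref$latents[[nm]]
    df <- data.frame(index = seq_len(nrow(rl)), rl, check.names = FALSE)
    names(df)[-1] <- sprintf("z%03d", seq_len(ncol(df) - 1))
    write_num_csv(df, file.path(outdir, sprintf("ref_latents_%s.csv", nm)))
    put(sprintf("ref_latents_%s.csv", nm))
  }
  rs <- data.frame(block = seq_len(nrow(session$ref$scores)),
                   session$ref$scores, check.names = FALSE)
  write_num_csv(rs, file.path(outdir, "ref_scores.csv"))
  put("ref_scores.csv")

  # spike records: one row per trial (spike times packed, ';'-separated),
  # so spikeless trials survive the round trip
  sp <- do.call(rbind, lapply(names(session$spikes), function(key) {
    recs <- session$spikes[[key]]
    do.call(rbind, lapply(recs, function(r) {
      data.frame(key = key, image_id = r$image_id, block_id = r$block_id,
                 trial_id = r$trial_id,
                 spike_times_ms = paste(fmt_num(r$spike_times),
                                        collapse = ";"))
    }))
  }))
  utils::write.csv(sp, file.path(outdir, "spikes.csv"), row.names = FALSE)
  put("spikes.csv")

  pres <- do.call(rbind, lapply(seq_along(session$presentation), function(b) {
    data.frame(block = b, order = seq_along(session$presentation[[b]]),
               image_id = session$presentation[[b]])
  }))
  utils::write.csv(pres, file.path(outdir, "presentation.csv"),
                   row.names = FALSE)
  put("presentation.csv")

  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- list(artifact = "evomanifold_session",
                   version = as.character(utils::packageVersion("evomanifold")),
                   master_seed = session$master_seed,
                   files = lapply(seq_along(files), function(i) {
                     list(name = files[i], md5 = unname(sums[i]))
                   }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load an evolution session from a manifest
#'
#' Verifies every checksum before reading; a missing file or checksum
#' mismatch aborts with an error naming the file.
#'
#' @param path a session directory or its `manifest.json`.
#' @return The reconstructed `evolution_session`.
#' @export
load_session <- function(path) {
  mf <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  if (!file.exists(mf)) stop("manifest not found: ", mf)
  manifest <- jsonlite::read_json(mf)
  outdir <- dirname(mf)
  for (f in manifest$files) {
    fp <- file.path(outdir, f$name)
    if (!file.exists(fp)) stop("manifest references absent file: ", f$name)
    sum <- unname(tools::md5sum(fp))
    if (!identical(sum, f$md5)) {
      stop("checksum mismatch for file: ", f$name)
    }
  }
  meta <- jsonlite::read_json(file.path(outdir, "session.json"),
                              simplifyVector = TRUE)
  required <- c("config", "master_seed", "generators", "neuron", "ref_ids")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("session schema error: missing field(s) ", paste(missing, collapse = ", "))
  }
  config <- meta$config
  config$window <- as.numeric(config$window)
  neuron <- deserialize_neuron(meta$neuron)
  gens <- lapply(meta$generators, function(g) {
    list(fun = g$fun, args = as.list(g$args))
  })

  threads <- list()
  for (th in c("a", "b")) {
    lat <- utils::read.csv(file.path(outdir, sprintf("thread_%s_latents.csv", th)))
    sc <- utils::read.csv(file.path(outdir, sprintf("thread_%s_scores.csv", th)))
    trc <- utils::read.csv(file.path(outdir, sprintf("thread_%s_trace.csv", th)))
    blocks <- sort(unique(lat$block))
    tr <- list(generator = if (th == "a") meta$generators$a$args$n_basis else NULL,
               latents = lapply(blocks, function(b) {
                 unname(as.matrix(lat[lat$block == b, -(1:2), drop = FALSE]))
               }),
               scores = lapply(blocks, function(b) sc$score_spk_s[sc$block == b]),
               image_ids = lapply(blocks, function(b) sc$image_id[sc$block == b]),
               trace = list(means = unname(as.matrix(trc[, -(1:2), drop = FALSE])),
                            sigma = trc$sigma))
    tr$generator <- if (grepl("texture", gens[[th]]$fun)) "texture" else "object"
    class(tr) <- "evolution_thread"
    threads[[th]] <- tr
  }

  ref_lat <- lapply(c(a = "a", b = "b"), function(nm) {
    df <- utils::read.csv(file.path(outdir, sprintf("ref_latents_%s.csv", nm)))
    unname(as.matrix(df[, -1, drop = FALSE]))
  })
  rs <- utils::read.csv(file.path(outdir, "ref_scores.csv"), check.names = FALSE)
  ref_scores <- as.matrix(rs[, -1, drop = FALSE])
  rownames(ref_scores) <- NULL

  spdf <- utils::read.csv(file.path(outdir, "spikes.csv"),
                          colClasses = c(spike_times_ms = "character"))
  spikes <- list()
  if (nrow(spdf)) {
    for (key in unique(spdf$key)) {
      rows <- spdf[spdf$key == key, , drop = FALSE]
      spikes[[key]] <- lapply(seq_len(nrow(rows)), function(i) {
        st <- rows$spike_times_ms[i]
        list(image_id = rows$image_id[i], block_id = rows$block_id[i],
             trial_id = rows$trial_id[i],
             spike_times = if (nzchar(st)) as.numeric(strsplit(st, ";")[[1]])
                           else numeric(0))
      })
    }
  }
  pres <- utils::read.csv(file.path(outdir, "presentation.csv"))
  presentation <- lapply(sort(unique(pres$block)), function(b) {
    pres$image_id[pres$block == b][order(pres$order[pres$block == b])]
  })

  structure(list(neuron = neuron, threads = threads, generators = gens,
                 final_mean = lapply(meta$final_mean, as.numeric),
                 ref = list(ids = meta$ref_ids, latents = ref_lat,
                            scores = ref_scores),
                 spikes = spikes, presentation = presentation,
                 config = config, master_seed = meta$master_seed,
                 log = unlist(meta$log) %||% character()),
            class = "evolution_session")
}

#' Export session stimuli as PNG files
#'
#' Re-renders stored latents through the session's generators and writes
#' one PNG per requested image via the grDevices png device.
#'
#' @param session an `evolution_session`.
#' @param outdir output directory.
#' @param blocks which blocks to export (default: final block only).
#' @return Character vector of written paths (invisibly).
#' @export
export_stimuli_png <- function(session, outdir, blocks = NULL) {
  if (!capabilities("png")) stop("png device not available")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gens <- session_generators(session)
  if (is.null(blocks)) blocks <- session$config$blocks
  written <- character()
  for (th in c("a", "b")) {
    for (b in blocks) {
      lat <- session$threads[[th]]$latents[[b]]
      ids <- session$threads[[th]]$image_ids[[b]]
      for (i in seq_len(nrow(lat))) {
        img <- render_image(gens[[th]], lat[i, ])
        fp <- file.path(outdir, paste0(ids[i], ".png"))
        grDevices::png(fp, width = dim(img)[2], height = dim(img)[1])
        graphics::par(mar = c(0, 0, 0, 0))
        graphics::plot.new()
        graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
        grDevices::dev.off()
        written <- c(written, fp)
      }
    }
  }
  invisible(written)
}
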