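#' Read waveforms from a CSV file
#'
#' Two dialects are supported. The canonical *long* dialect has one row per
#' sample with columns `subject_id, group, sex, eye, flash_td,
#' recording_index, sample_index, amplitude_uv`; `sample_index` is 0-based
#' and contiguous within a recording. The *wide* dialect has one row per
#' recording with the same metadata columns followed by amplitude columns
#' `s0 ... s{N-1}`.
#'
#' Empty `group`/`sex`/`eye` fields map to `"UNKNOWN"`; an empty `flash_td`
#' maps to `NA`. Recordings containing missing amplitude values are dropped
#' with a warning.
#'
#' @param path CSV file path.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param sampling_rate Sampling rate (Hz) to attach; the dialect carries no
#'   rate column because the acquisition protocol fixes it (default 2000).
#' @return A list of [waveform()] objects, one per
#'   (subject, eye, flash, recording) combination.
#' @export
read_waveforms <- function(path, dialect = c("long", "wide"),
                           sampling_rate = 2000) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  meta_cols <- c("subject_id", "group", "sex", "eye", "flash_td",
                 "recording_index")
  need <- if (dialect == "long") c(meta_cols, "sample_index", "amplitude_uv")
          else meta_cols
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("malformed header: missing column(s) ",
         paste(missing_cols, collapse = ", "))

  blank_to <- function(x, default) {
    x <- as.character(x)
    x[is.na(x) | x == ""] <- default
    x
  }
  df$group <- blank_to(df$group, "UNKNOWN")
  df$sex <- blank_to(df$sex, "UNKNOWN")
  df$eye <- blank_to(df$eye, "UNKNOWN")
  df$flash_td <- suppressWarnings(as.numeric(df$flash_td))

  if (dialect == "long") {
    key <- paste(df$subject_id, df$eye, df$flash_td, df$recording_index,
                 sep = "\r")
    if (anyDuplicated(paste(key, df$sample_index)))
      stop("data error: duplicated (subject, eye, flash, recording, sample_index) rows")
    out <- lapply(split(df, key), function(d) {
      d <- d[order(d$sample_index), , drop = FALSE]
      if (!identical(as.integer(d$sample_index),
                     seq_len(nrow(d)) - 1L))
        stop("data error: sample_index not 0-based contiguous for subject ",
             d$subject_id[1])
      if (anyNA(d$amplitude_uv)) return(NULL)
      waveform(d$amplitude_uv, sampling_rate = sampling_rate,
               subject_id = d$subject_id[1], group = d$group[1],
               sex = d$sex[1], eye = d$eye[1], flash_td = d$flash_td[1],
               recording_index = d$recording_index[1])
    })
  } else {
    scol <- grep("^s[0-9]+$", names(df), value = TRUE)
    if (length(scol) == 0)
      stop("malformed header: missing column(s) s0...")
    scol <- scol[order(as.integer(sub("^s", "", scol)))]
    out <- lapply(seq_len(nrow(df)), function(i) {
      amp <- as.numeric(df[i, scol])
      if (anyNA(amp)) return(NULL)
      waveform(amp, sampling_rate = sampling_rate,
               subject_id = df$subject_id[i], group = df$group[i],
               sex = df$sex[i], eye = df$eye[i], flash_td = df$flash_td[i],
               recording_index = df$recording_index[i])
    })
  }
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " recording(s) dropped due to missing amplitude values")
  unname(Filter(Negate(is.null), out))
}

#' Write waveforms to a CSV file
#'
#' Inverse of [read_waveforms()]: `read_waveforms(write_waveforms(x))`
#' reproduces samples and metadata bit for bit (amplitudes are written with
#' 17 significant digits). `UNKNOWN` enum values are written as empty
#' fields.
#'
#' @param waves Non-empty list of [waveform()] objects.
#' @param path Output CSV path.
#' @param dialect `"long"` (default) or `"wide"` (requires equal lengths).
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(waves, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (length(waves) == 0) stop("cannot write an empty waveform collection")
  stopifnot(all(vapply(waves, is_waveform, logical(1))))
  enum_out <- function(x) ifelse(x == "UNKNOWN", "", x)
  fmt <- function(x) sprintf("%.17g", x)
  meta <- function(w) data.frame(
    subject_id = w$subject_id, group = enum_out(w$group),
    sex = enum_out(w$sex), eye = enum_out(w$eye),
    flash_td = ifelse(is.na(w$flash_td), "", fmt(w$flash_td)),
    recording_index = w$recording_index, stringsAsFactors = FALSE)
  if (dialect == "long") {
    df <- do.call(rbind, lapply(waves, function(w) {
      cbind(meta(w)[rep(1, w$n_samples), , drop = FALSE],
            data.frame(sample_index = seq_len(w$n_samples) - 1L,
                       amplitude_uv = fmt(w$samples)))
    }))
  } else {
    ns <- vapply(waves, function(w) w$n_samples, integer(1))
    if (length(unique(ns)) != 1)
      stop("wide dialect requires all waveforms to have equal length")
    amp <- do.call(rbind, lapply(waves, function(w) fmt(w$samples)))
    colnames(amp) <- paste0("s", seq_len(ns[1]) - 1L)
    df <- cbind(do.call(rbind, lapply(waves, meta)), as.data.frame(amp))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a feature table CSV
#'
#' One row per (waveform, construction, Q): metadata columns first, then
#' feature columns. Numeric values are written with 17 significant digits
#' so the round trip is exact.
#'
#' @param tbl A feature table (tibble/data.frame), e.g. from
#'   [extract_feature_table()].
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a tibble.
#' @export
write_feature_table <- function(tbl, path) {
  df <- as.data.frame(tbl)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  # real-valued feature columns parse as integer when they happen to hold
  # whole numbers; restore their double type (gnc is a true integer count)
  dbl <- c(setdiff(feature_names(), "gnc"),
           grep("^td_", names(df), value = TRUE))
  for (col in intersect(dbl, names(df))) df[[col]] <- as.numeric(df[[col]])
  tibble::as_tibble(df)
}

#' Export a signal graph
#'
#' Three plain-text formats: a weighted edge list (`u v weight count`, node
#' labels as written by the construction), GraphML (via igraph, keeping
#' `weight` and `count` edge attributes), and MatrixMarket coordinate
#' format for the symmetric adjacency matrix (self-loops excluded, as in
#' the spectral views).
#'
#' @param g A `signal_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_edgelist <- function(g, path) {
  stopifnot(inherits(g, "signal_graph"))
  e <- g$edges
  lines <- c("u v weight count",
             sprintf("%s %s %.17g %d", g$node_labels[e$i], g$node_labels[e$j],
                     e$weight, e$count))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graph_edgelist
#' @export
write_graph_graphml <- function(g, path) {
  stopifnot(inherits(g, "signal_graph"))
  ig <- as_igraph(g, include_self_loops = TRUE)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graph_edgelist
#' @export
write_graph_mtx <- function(g, path) {
  stopifnot(inherits(g, "signal_graph"))
  s <- spectral_summary(g)
  Matrix::writeMM(Matrix::Matrix(s$adjacency, sparse = TRUE), path)
  invisible(path)
}

#' Read a signal graph back from an edge-list export
#'
#' @param path File written by [write_graph_edgelist()].
#' @param Q Quantization resolution to attach (optional).
#' @return A `signal_graph` with the same nodes, weights and counts.
#' @export
read_graph_edgelist <- function(path, Q = NA_integer_) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(u = "character", v = "character"))
  labels <- sort(unique(c(df$u, df$v)))
  i <- match(df$u, labels); j <- match(df$v, labels)
  sw <- pmin(i, j); j <- pmax(i, j); i <- sw
  values <- suppressWarnings(as.numeric(labels))
  new_signal_graph(node_labels = labels, node_values = values,
                   edges = data.frame(i = i, j = j, weight = df$weight,
                                      count = as.integer(df$count)),
                   Q = Q, construction = "ERG_GRAPH", n_source = NA_integer_)
}
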