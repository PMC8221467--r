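# Landmark dataset containers and file dialects.
#
# A dataset is stored as a k x 3 x n array (landmarks x axes x specimens)
# plus a metadata data.frame, mirroring the p x k x n convention of the
# major morphometrics packages.

#' Group levels recognised by the study design
#'
#' Four skeletal samples: two Anglo-Saxon target groups whose ancestry is to
#' be estimated, and two candidate source groups (Pre-Medieval British and
#' Danish Iron Age).
#'
#' @export
GROUP_LEVELS <- c("EARLY_AS", "MIDDLE_AS", "PREMED_BRITISH", "DANISH")

#' @rdname GROUP_LEVELS
#' @export
SOURCE_GROUPS <- c("PREMED_BRITISH", "DANISH")

#' @rdname GROUP_LEVELS
#' @export
TARGET_GROUPS <- c("EARLY_AS", "MIDDLE_AS")

#' Role of a group in the attribution design
#'
#' Source groups supply the known reference samples for the discriminant
#' analysis; target groups are the samples whose ancestry is estimated.
#' The role is a pure function of the group name.
#'
#' @param group character vector of group names.
#' @return character vector, `"SOURCE"` or `"TARGET"`.
#' @export
group_role <- function(group) {
  ifelse(as.character(group) %in% SOURCE_GROUPS, "SOURCE", "TARGET")
}

#' Construct a single landmark configuration
#'
#' @param specimen_id character scalar.
#' @param coords numeric k x 3 matrix of Cartesian coordinates (k >= 3).
#' @param labels optional character vector of k unique landmark labels;
#'   defaults to the rownames of `coords` or `lm1..lmk`.
#' @return an object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, coords, labels = NULL) {
  check_matrix3(coords, paste0("coords for '", specimen_id, "'"))
  k <- nrow(coords)
  if (k < 3L) stop_cm("a configuration needs at least 3 landmarks")
  labels <- labels %||% rownames(coords) %||% paste0("lm", seq_len(k))
  if (length(labels) != k) stop_cm("labels length must equal landmark count")
  if (anyDuplicated(labels)) stop_cm("landmark labels must be unique")
  rownames(coords) <- labels
  colnames(coords) <- c("x", "y", "z")
  structure(
    list(specimen_id = as.character(specimen_id), coords = coords,
         labels = as.character(labels)),
    class = "landmark_config"
  )
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration '", x$specimen_id, "': ",
      nrow(x$coords), " landmarks\n", sep = "")
  invisible(x)
}

#' Assemble a shape dataset from configurations and metadata
#'
#' All configurations must share the same landmark count and label order,
#' and specimen ids must be unique.  Metadata rows are joined by
#' `specimen_id`; every configuration must have exactly one record when
#' metadata is supplied.
#'
#' @param configs list of [landmark_config()] objects, or a k x 3 x n array.
#' @param meta optional data.frame with columns `specimen_id`, `group`,
#'   `sex` and optionally `site`.
#' @param scheme optional [symmetry_scheme()] carried along for reference.
#' @return an object of class `shape_dataset`.
#' @export
shape_dataset <- function(configs, meta = NULL, scheme = NULL) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    arr <- configs
    if (dim(arr)[2] != 3L) stop_cm("coordinate array must be k x 3 x n")
    ids <- dimnames(arr)[[3]] %||% paste0("spec", seq_len(dim(arr)[3]))
    labels <- dimnames(arr)[[1]] %||% paste0("lm", seq_len(dim(arr)[1]))
  } else {
    if (!length(configs)) stop_cm("empty configuration list")
    configs <- lapply(configs, function(cf) {
      if (!inherits(cf, "landmark_config")) stop_cm("configs must be landmark_config objects")
      cf
    })
    k <- nrow(configs[[1]]$coords)
    labels <- configs[[1]]$labels
    for (cf in configs) {
      if (nrow(cf$coords) != k) {
        stop_cm("specimen '", cf$specimen_id, "' has ", nrow(cf$coords),
                " landmarks; expected ", k)
      }
      if (!identical(cf$labels, labels)) {
        stop_cm("specimen '", cf$specimen_id, "' has a different landmark label order")
      }
    }
    ids <- vapply(configs, `[[`, character(1), "specimen_id")
    arr <- array(NA_real_, dim = c(k, 3L, length(configs)))
    for (i in seq_along(configs)) arr[, , i] <- configs[[i]]$coords
  }
  if (anyDuplicated(ids)) stop_cm("specimen ids must be unique")
  if (!all(is.finite(arr))) stop_cm("dataset contains missing or non-finite coordinates")
  dimnames(arr) <- list(labels, c("x", "y", "z"), ids)

  if (is.null(meta)) {
    meta <- data.frame(specimen_id = ids, group = NA_character_,
                       sex = NA_character_, site = NA_character_,
                       stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (!"specimen_id" %in% names(meta)) stop_cm("metadata needs a specimen_id column")
    meta$specimen_id <- as.character(meta$specimen_id)
    missing_ids <- setdiff(ids, meta$specimen_id)
    if (length(missing_ids)) {
      stop_cm("no metadata record for specimen(s): ",
              paste(missing_ids, collapse = ", "))
    }
    unknown <- setdiff(meta$specimen_id, ids)
    if (length(unknown)) {
      stop_cm("metadata names unknown specimen(s): ",
              paste(unknown, collapse = ", "))
    }
    if (anyDuplicated(meta$specimen_id)) stop_cm("duplicate metadata records")
    meta <- meta[match(ids, meta$specimen_id), , drop = FALSE]
    if (!"group" %in% names(meta)) meta$group <- NA_character_
    if (!"sex" %in% names(meta)) meta$sex <- NA_character_
    if (!"site" %in% names(meta)) meta$site <- NA_character_
    bad_sex <- !is.na(meta$sex) & !meta$sex %in% c("F", "M")
    if (any(bad_sex)) stop_cm("sex must be 'F' or 'M' (specimen ",
                              meta$specimen_id[bad_sex][1], ")")
  }
  meta$role <- ifelse(is.na(meta$group), NA_character_, group_role(meta$group))
  rownames(meta) <- NULL
  structure(list(coords = arr, meta = meta, scheme = scheme),
            class = "shape_dataset")
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat("Shape dataset: ", n_specimens(x), " specimens, ",
      n_landmarks(x), " landmarks\n", sep = "")
  if (!all(is.na(x$meta$group))) {
    print(table(group = x$meta$group, sex = x$meta$sex, useNA = "ifany"))
  }
  invisible(x)
}

#' @export
#' @rdname shape_dataset
n_specimens <- function(dataset) dim(dataset$coords)[3]

#' @export
#' @rdname shape_dataset
n_landmarks <- function(dataset) dim(dataset$coords)[1]

#' @export
#' @rdname shape_dataset
specimen_ids <- function(dataset) dimnames(dataset$coords)[[3]]

#' Extract one configuration from a dataset
#' @param dataset a `shape_dataset`.
#' @param i specimen index or id.
#' @return a [landmark_config()].
#' @export
get_config <- function(dataset, i) {
  if (is.character(i)) i <- match(i, specimen_ids(dataset))
  landmark_config(specimen_ids(dataset)[i],
                  dataset$coords[, , i, drop = TRUE],
                  dimnames(dataset$coords)[[1]])
}

#' Flatten a dataset to an n x 3k matrix
#'
#' Row per specimen; columns ordered `lm1_x, lm1_y, lm1_z, lm2_x, ...`.
#'
#' @param dataset a `shape_dataset`.
#' @return numeric matrix.
#' @export
flatten_coords <- function(dataset) {
  arr <- dataset$coords
  k <- dim(arr)[1]; n <- dim(arr)[3]
  out <- matrix(NA_real_, n, 3L * k)
  for (i in seq_len(n)) out[i, ] <- as.vector(t(arr[, , i]))
  labels <- dimnames(arr)[[1]]
  colnames(out) <- as.vector(t(outer(labels, c("x", "y", "z"), paste, sep = "_")))
  rownames(out) <- dimnames(arr)[[3]]
  out
}

# Inverse of flatten_coords for one row vector.
unflatten_coords <- function(v, k) {
  matrix(v, nrow = k, ncol = 3L, byrow = TRUE)
}

#' Subset a dataset by sex and/or group
#'
#' @param dataset a `shape_dataset`.
#' @param sex optional `"F"` or `"M"`.
#' @param groups optional character vector of group names; all must be
#'   present in the dataset.
#' @return a `shape_dataset` with the matching specimens in original order.
#'   An empty result triggers a warning, not an error.
#' @export
subset_specimens <- function(dataset, sex = NULL, groups = NULL) {
  keep <- rep(TRUE, n_specimens(dataset))
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("F", "M"))
    keep <- keep & !is.na(dataset$meta$sex) & dataset$meta$sex == sex
  }
  if (!is.null(groups)) {
    absent <- setdiff(groups, unique(dataset$meta$group))
    if (length(absent)) {
      stop_cm("requested group(s) not present: ", paste(absent, collapse = ", "))
    }
    keep <- keep & !is.na(dataset$meta$group) & dataset$meta$group %in% groups
  }
  if (!any(keep)) warning("subset is empty", call. = FALSE)
  idx <- which(keep)
  structure(list(coords = dataset$coords[, , idx, drop = FALSE],
                 meta = dataset$meta[idx, , drop = FALSE],
                 scheme = dataset$scheme),
            class = "shape_dataset")
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Read a landmark dataset
#'
#' Supported dialects:
#' \describe{
#'   \item{csv}{header `specimen_id,group,sex[,site],lm1_x,lm1_y,lm1_z,...`;
#'     metadata columns are optional and joined inline.}
#'   \item{whitespace}{`layout = "specimen"`: one row per specimen,
#'     `id x1 y1 z1 x2 ...`; `layout = "landmark"`: one row per landmark,
#'     `id x y z`, consecutive rows grouped by id.}
#'   \item{tps}{`LM3=k` blocks of k coordinate lines followed by `ID=`.}
#'   \item{morphologika}{`[individuals]`, `[landmarks]`, `[dimensions]`,
#'     `[names]`, `[rawpoints]` sections.}
#' }
#'
#' @param path input file.
#' @param dialect one of `"csv"`, `"whitespace"`, `"tps"`, `"morphologika"`.
#' @param metadata_path optional delimited table (`specimen_id,group,sex[,site]`)
#'   joined by specimen id.
#' @param layout row layout for the whitespace dialect.
#' @return a [shape_dataset()].
#' @export
read_landmarks <- function(path,
                           dialect = c("csv", "whitespace", "tps", "morphologika"),
                           metadata_path = NULL,
                           layout = c("specimen", "landmark")) {
  dialect <- match.arg(dialect)
  layout <- match.arg(layout)
  if (!file.exists(path)) stop_cm("file not found: ", path)
  parsed <- switch(dialect,
    csv = read_lm_csv(path),
    whitespace = read_lm_whitespace(path, layout),
    tps = read_lm_tps(path),
    morphologika = read_lm_morphologika(path)
  )
  meta <- parsed$meta
  if (!is.null(metadata_path)) {
    ext_meta <- read_metadata_table(metadata_path)
    meta <- ext_meta
  }
  shape_dataset(parsed$configs, meta = meta)
}

read_metadata_table <- function(path) {
  if (!file.exists(path)) stop_cm("metadata file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, strip.white = TRUE)
}

read_lm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"specimen_id" %in% names(df)) stop_cm("CSV needs a specimen_id column")
  coord_cols <- grep("_(x|y|z)$", names(df), value = TRUE)
  if (!length(coord_cols) || length(coord_cols) %% 3L != 0L) {
    stop_cm("CSV coordinate columns must come in _x/_y/_z triples")
  }
  lm_names <- unique(sub("_(x|y|z)$", "", coord_cols))
  configs <- lapply(seq_len(nrow(df)), function(i) {
    m <- matrix(NA_real_, length(lm_names), 3L)
    for (j in seq_along(lm_names)) {
      m[j, ] <- as.numeric(df[i, paste0(lm_names[j], c("_x", "_y", "_z"))])
    }
    landmark_config(df$specimen_id[i], m, lm_names)
  })
  meta_cols <- intersect(c("specimen_id", "group", "sex", "site"), names(df))
  meta <- if (length(meta_cols) > 1L) df[, meta_cols, drop = FALSE] else NULL
  list(configs = configs, meta = meta)
}

read_lm_whitespace <- function(path, layout) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  if (layout == "specimen") {
    configs <- lapply(toks, function(tk) {
      vals <- suppressWarnings(as.numeric(tk[-1]))
      if (anyNA(vals) || length(vals) %% 3L != 0L) {
        stop_cm("malformed row for specimen '", tk[1], "'")
      }
      landmark_config(tk[1], unflatten_coords(vals, length(vals) / 3L))
    })
  } else {
    ids <- vapply(toks, `[[`, character(1), 1L)
    runs <- rle(ids)
    configs <- vector("list", length(runs$values))
    pos <- 0L
    for (r in seq_along(runs$values)) {
      rows <- toks[pos + seq_len(runs$lengths[r])]
      pos <- pos + runs$lengths[r]
      m <- t(vapply(rows, function(tk) {
        v <- suppressWarnings(as.numeric(tk[2:4]))
        if (anyNA(v) || length(tk) < 4L) {
          stop_cm("malformed row for specimen '", tk[1], "'")
        }
        v
      }, numeric(3)))
      configs[[r]] <- landmark_config(runs$values[r], m)
    }
  }
  list(configs = configs, meta = NULL)
}

read_lm_tps <- function(path) {
  lines <- trimws(readLines(path))
  configs <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^LM3\\s*=", ln, ignore.case = TRUE)) {
      k <- as.integer(sub("^LM3\\s*=\\s*", "", ln, ignore.case = TRUE))
      coord_lines <- lines[i + seq_len(k)]
      m <- t(vapply(strsplit(coord_lines, "[[:space:]]+"), function(tk) {
        v <- suppressWarnings(as.numeric(tk))
        if (length(v) != 3L || anyNA(v)) stop_cm("malformed TPS coordinate line")
        v
      }, numeric(3)))
      i <- i + k + 1L
      id <- paste0("spec", length(configs) + 1L)
      while (i <= length(lines) && !grepl("^LM3\\s*=", lines[i], ignore.case = TRUE)) {
        if (grepl("^ID\\s*=", lines[i], ignore.case = TRUE)) {
          id <- sub("^ID\\s*=\\s*", "", lines[i], ignore.case = TRUE)
        }
        i <- i + 1L
      }
      configs[[length(configs) + 1L]] <- landmark_config(id, m)
    } else {
      i <- i + 1L
    }
  }
  if (!length(configs)) stop_cm("no LM3 blocks found in TPS file")
  list(configs = configs, meta = NULL)
}

read_lm_morphologika <- function(path) {
  lines <- trimws(readLines(path))
  sec <- function(name) {
    hit <- grep(paste0("^\\[", name, "\\]$"), lines, ignore.case = TRUE)
    if (!length(hit)) stop_cm("morphologika file lacks [", name, "] section")
    hit[1]
  }
  n <- as.integer(lines[sec("individuals") + 1L])
  k <- as.integer(lines[sec("landmarks") + 1L])
  dims <- as.integer(lines[sec("dimensions") + 1L])
  if (!identical(dims, 3L)) stop_cm("only 3D morphologika files are supported")
  names_at <- sec("names")
  ids <- lines[names_at + seq_len(n)]
  raw_at <- sec("rawpoints")
  body <- lines[(raw_at + 1L):length(lines)]
  body <- body[nzchar(body) & !startsWith(body, "'")]
  vals <- t(vapply(strsplit(body, "[[:space:]]+"), function(tk) {
    v <- suppressWarnings(as.numeric(tk))
    if (length(v) != 3L || anyNA(v)) stop_cm("malformed morphologika coordinate line")
    v
  }, numeric(3)))
  if (nrow(vals) != n * k) {
    stop_cm("morphologika file has ", nrow(vals), " coordinate rows; expected ", n * k)
  }
  configs <- lapply(seq_len(n), function(i) {
    landmark_config(ids[i], vals[(i - 1L) * k + seq_len(k), , drop = FALSE])
  })
  list(configs = configs, meta = NULL)
}

#' Write a landmark dataset
#'
#' Inverse of [read_landmarks()]; coordinates are written with full double
#' precision so a read/write cycle is lossless.
#'
#' @param dataset a `shape_dataset`.
#' @param path output file.
#' @param dialect output format, as in [read_landmarks()].
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(dataset, path,
                            dialect = c("csv", "whitespace", "tps", "morphologika")) {
  dialect <- match.arg(dialect)
  k <- n_landmarks(dataset); n <- n_specimens(dataset)
  ids <- specimen_ids(dataset)
  switch(dialect,
    csv = {
      flat <- flatten_coords(dataset)
      df <- data.frame(specimen_id = ids,
                       group = dataset$meta$group,
                       sex = dataset$meta$sex,
                       stringsAsFactors = FALSE)
      flat_chr <- apply(flat, 2, fmt_num)
      if (n == 1L) flat_chr <- matrix(flat_chr, nrow = 1L,
                                      dimnames = list(NULL, colnames(flat)))
      df <- cbind(df, as.data.frame(flat_chr, stringsAsFactors = FALSE))
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    },
    whitespace = {
      flat <- flatten_coords(dataset)
      lines <- vapply(seq_len(n), function(i) {
        paste(c(ids[i], fmt_num(flat[i, ])), collapse = " ")
      }, character(1))
      writeLines(lines, path)
    },
    tps = {
      con <- file(path, "w"); on.exit(close(con))
      for (i in seq_len(n)) {
        writeLines(paste0("LM3=", k), con)
        m <- dataset$coords[, , i]
        writeLines(apply(m, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
        writeLines(paste0("ID=", ids[i]), con)
      }
    },
    morphologika = {
      con <- file(path, "w"); on.exit(close(con))
      writeLines(c("[individuals]", n, "[landmarks]", k, "[dimensions]", 3,
                   "[names]", ids, "[rawpoints]"), con)
      for (i in seq_len(n)) {
        writeLines(paste0("'", ids[i]), con)
        m <- dataset$coords[, , i]
        writeLines(apply(m, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
      }
    }
  )
  invisible(path)
}

#' Write a specimen metadata table
#'
#' Companion to the whitespace/TPS/morphologika dialects, which carry no
#' metadata of their own.
#'
#' @param dataset a `shape_dataset`.
#' @param path output CSV file.
#' @export
write_metadata <- function(dataset, path) {
  utils::write.csv(dataset$meta[, c("specimen_id", "group", "sex", "site")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
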