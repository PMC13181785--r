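# File formats: Bruker 1D fid/acqus (read + fixture write), JCAMP-DX
# (read/write, NTUPLES real/imaginary pages), the dataset container
# (flat little-endian float64 block + JSON manifest), and the merged run
# configuration.

# -- Bruker ------------------------------------------------------------------

parse_acqus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get <- function(key, default = NULL) {
    hit <- grep(sprintf("^##\\$%s=", key), lines, value = TRUE)
    if (length(hit) == 0) {
      if (is.null(default)) stop("acqus: missing required parameter ", key)
      return(default)
    }
    trimws(sub("^##\\$[A-Za-z_0-9]+=", "", hit[1]))
  }
  list(td = as.integer(get("TD")),
       sw_h = as.numeric(get("SW_h")),
       grpdly = as.numeric(get("GRPDLY", "0")),
       bytorda = as.integer(get("BYTORDA", "0")),
       dtypa = as.integer(get("DTYPA", "0")))
}

#' Read a Bruker 1D FID directory
#'
#' Expects the standard layout: a binary `fid` file with interleaved
#' real/imaginary samples and an `acqus` text file supplying TD (total
#' real+imaginary point count), SW_h (spectral width, Hz), GRPDLY
#' (digital-filter group delay, points), BYTORDA (0 = little endian,
#' 1 = big endian) and DTYPA (0 = int32, 2 = float64).
#'
#' @param dir Path to the experiment directory.
#' @return A [fid_record()] with `dwell_time = 1 / SW_h`.
#' @export
read_bruker_fid <- function(dir) {
  fid_path <- file.path(dir, "fid")
  acqus_path <- file.path(dir, "acqus")
  if (!file.exists(acqus_path)) stop("read_bruker_fid: no acqus file in ", dir)
  if (!file.exists(fid_path)) stop("read_bruker_fid: no fid file in ", dir)
  p <- parse_acqus(acqus_path)
  if (p$td %% 2 != 0 || p$td < 4) stop("read_bruker_fid: TD must be even and >= 4")
  if (p$sw_h <= 0) stop("read_bruker_fid: SW_h must be > 0")
  endian <- if (p$bytorda == 1) "big" else "little"
  sz <- file.size(fid_path)
  if (p$dtypa == 0) {
    expected <- p$td * 4
    what <- "integer"; size <- 4
  } else if (p$dtypa == 2) {
    expected <- p$td * 8
    what <- "numeric"; size <- 8
  } else {
    stop("read_bruker_fid: unknown DTYPA ", p$dtypa, " (supported: 0 = int32, 2 = float64)")
  }
  if (sz != expected)
    stop(sprintf("read_bruker_fid: fid size mismatch: expected %d bytes for TD=%d, found %d",
                 expected, p$td, sz))
  con <- file(fid_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, what, n = p$td, size = size, endian = endian)
  re <- raw_vals[seq(1, p$td, by = 2)]
  im <- raw_vals[seq(2, p$td, by = 2)]
  fid_record(complex(real = re, imaginary = im), dwell_time = 1 / p$sw_h,
             group_delay = p$grpdly)
}

#' Write a Bruker-layout FID fixture directory
#'
#' Writes `fid` + `acqus` in the subset of the Bruker layout that
#' [read_bruker_fid()] consumes; intended for tests and round-trip checks.
#'
#' @param fid A [fid_record()].
#' @param dir Output directory (created if needed).
#' @param byte_order `"little"` or `"big"`.
#' @param data_type `"int32"` or `"float64"`.
#' @return `dir`, invisibly.
#' @export
write_bruker_fixture <- function(fid, dir, byte_order = "little",
                                 data_type = "float64") {
  stopifnot(inherits(fid, "fid_record"),
            byte_order %in% c("little", "big"),
            data_type %in% c("int32", "float64"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(fid$samples)
  inter <- as.vector(rbind(Re(fid$samples), Im(fid$samples)))
  acqus <- c("##TITLE= Parameter file",
             "##JCAMP-DX= 5.0",
             sprintf("##$TD= %d", 2L * n),
             sprintf("##$SW_h= %.10g", 1 / fid$dwell_time),
             sprintf("##$GRPDLY= %.10g", fid$group_delay),
             sprintf("##$BYTORDA= %d", if (byte_order == "big") 1L else 0L),
             sprintf("##$DTYPA= %d", if (data_type == "int32") 0L else 2L),
             "##END=")
  writeLines(acqus, file.path(dir, "acqus"))
  con <- file(file.path(dir, "fid"), "wb")
  on.exit(close(con))
  if (data_type == "int32") {
    writeBin(as.integer(round(inter)), con, size = 4, endian = byte_order)
  } else {
    writeBin(as.numeric(inter), con, size = 8, endian = byte_order)
  }
  invisible(dir)
}

# -- JCAMP-DX ----------------------------------------------------------------

#' Write a spectrum to JCAMP-DX
#'
#' Writes an NTUPLES record with real and imaginary data pages in plain
#' (AFFN) encoding.  Values survive a write/read round trip to better than
#' 1e-6 relative.
#'
#' @param spec A [spectrum1d()].
#' @param path Output file.
#' @param title Record title.
#' @return `path`, invisibly.
#' @export
write_jcamp <- function(spec, path, title = "nmrphaser spectrum") {
  stopifnot(inherits(spec, "spectrum1d"))
  n <- length(spec$points)
  fmt_page <- function(vals, sym) {
    c(sprintf("##PAGE= N=%d", if (sym == "R") 1L else 2L),
      sprintf("##DATA TABLE= (X++(%s..%s)), XYDATA", sym, sym),
      vapply(seq(1, n, by = 6), function(i0) {
        i1 <- min(i0 + 5, n)
        paste(c(sprintf("%d", i0 - 1),
                sprintf("%.10g", vals[i0:i1])), collapse = " ")
      }, ""))
  }
  lines <- c(
    sprintf("##TITLE= %s", title),
    "##JCAMP-DX= 5.00",
    "##DATA TYPE= NMR SPECTRUM",
    "##DATA CLASS= NTUPLES",
    sprintf("##ORIGIN= nmrphaser"),
    "##OWNER= ",
    sprintf("##NPOINTS= %d", n),
    if (!is.null(spec$spectral_width))
      sprintf("##$SPECTRALWIDTH= %.10g", spec$spectral_width),
    "##NTUPLES= NMR SPECTRUM",
    "##VAR_NAME= INDEX, SPECTRUM/REAL, SPECTRUM/IMAG",
    "##SYMBOL= X, R, I",
    "##VAR_DIM= N, N, N",
    fmt_page(Re(spec$points), "R"),
    fmt_page(Im(spec$points), "I"),
    "##END NTUPLES= NMR SPECTRUM",
    "##END=")
  writeLines(lines, path)
  invisible(path)
}

#' Read a JCAMP-DX spectrum
#'
#' Reads the NTUPLES real/imaginary layout written by [write_jcamp()].  A
#' file without an imaginary page yields a real-only spectrum with a warning.
#'
#' @param path Input file.
#' @return A [spectrum1d()].
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^##TITLE=", lines[1]))
    stop("read_jcamp: line 1: not a JCAMP-DX file (missing ##TITLE=)")
  np_line <- grep("^##NPOINTS=", lines, value = TRUE)
  pages <- grep("^##PAGE=", lines)
  if (length(pages) == 0)
    stop(sprintf("read_jcamp: line %d: no ##PAGE= data pages found",
                 length(lines)))
  sw_line <- grep("^##\\$SPECTRALWIDTH=", lines, value = TRUE)
  sw <- if (length(sw_line)) as.numeric(sub(".*=", "", sw_line[1])) else NULL
  ends <- c(pages[-1], grep("^##END", lines)[1])
  read_page <- function(i0, i1) {
    tbl_line <- lines[i0 + 1]
    if (!grepl("^##DATA TABLE=", tbl_line))
      stop(sprintf("read_jcamp: line %d: expected ##DATA TABLE= after ##PAGE=", i0 + 1))
    rows <- lines[(i0 + 2):(i1 - 1)]
    rows <- rows[!grepl("^##", rows) & nzchar(trimws(rows))]
    vals <- lapply(strsplit(trimws(rows), "[ \t]+"), function(tok) {
      v <- suppressWarnings(as.numeric(tok))
      if (any(is.na(v))) stop("read_jcamp: non-numeric token in data table")
      v[-1]  # drop leading X value
    })
    unlist(vals)
  }
  sym_of <- function(i0) {
    m <- regmatches(lines[i0 + 1], regexpr("\\(X\\+\\+\\(([RI])", lines[i0 + 1]))
    if (length(m)) substr(m, nchar(m), nchar(m)) else NA_character_
  }
  re <- NULL; im <- NULL
  for (pi in seq_along(pages)) {
    sym <- sym_of(pages[pi])
    v <- read_page(pages[pi], ends[pi])
    if (identical(sym, "R")) re <- v
    if (identical(sym, "I")) im <- v
  }
  if (is.null(re)) stop("read_jcamp: no real data page found")
  if (is.null(im)) {
    warning("read_jcamp: no imaginary page; returning real-only spectrum")
    im <- numeric(length(re))
  }
  if (length(np_line)) {
    np <- as.integer(sub(".*=", "", np_line[1]))
    if (length(re) != np)
      stop(sprintf("read_jcamp: NPOINTS=%d but %d real values read", np, length(re)))
  }
  spectrum1d(complex(real = re, imaginary = im), spectral_width = sw)
}

# -- dataset container -------------------------------------------------------

#' Write a synthetic dataset to a portable container
#'
#' Layout: `<path>.json` holds the manifest (per-sample id, task, label,
#' length, true phases, seed, broad-peak flag) plus the byte offset of every
#' sample; `<path>.bin` holds, per sample, the real then the imaginary part
#' as little-endian float64.  Any language can read the pair.
#'
#' @param ds A [build_dataset()] result with materialized samples.
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  if (is.null(ds$samples)) stop("write_dataset: dataset was not materialized")
  man <- ds$manifest
  man$offset_bytes <- c(0, cumsum(2 * 8 * man$n_points))[seq_len(nrow(man))]
  jsonlite::write_json(
    list(format = "nmrphaser-dataset-v1", n_samples = nrow(man),
         manifest = man),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (s in ds$samples) {
    writeBin(Re(s$spectrum$points), con, size = 8, endian = "little")
    writeBin(Im(s$spectrum$points), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a dataset container written by [write_dataset()]
#'
#' @param path Path without extension.
#' @return A list with `manifest` (data frame) and `samples` (list of
#'   `training_sample`).
#' @export
read_dataset <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "nmrphaser-dataset-v1"))
    stop("read_dataset: unrecognized container format")
  man <- meta$manifest
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  samples <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    np <- man$n_points[i]
    re <- readBin(con, "numeric", n = np, size = 8, endian = "little")
    im <- readBin(con, "numeric", n = np, size = 8, endian = "little")
    samples[[i]] <- structure(
      list(spectrum = spectrum1d(complex(real = re, imaginary = im)),
           label = man$label[i], task = man$task[i],
           true_phase = phase_pair(man$ph0[i], man$ph1[i]),
           provenance = list(seed = man$seed[i], n_points = np,
                             has_broad = man$has_broad[i])),
      class = "training_sample")
  }
  list(manifest = man, samples = samples)
}

# -- run configuration -------------------------------------------------------

#' Merged run configuration
#'
#' Bundles the generator, network, training and phasing option sets with a
#' master seed; serializes losslessly and order-stably to JSON.
#'
#' @param synth A [synth_config()].
#' @param net A [net_config()].
#' @param train A [train_config()].
#' @param phaser A [phaser_options()].
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synth = synth_config(), net = net_config(),
                       train = train_config(), phaser = phaser_options(),
                       seed = 1) {
  structure(list(synth = synth, net = net, train = train, phaser = phaser,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize a run configuration to JSON
#' @param cfg A [run_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  plain <- lapply(unclass(cfg), function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path Input file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  listify <- function(ctor, vals)
    do.call(ctor, vals[intersect(names(vals), names(formals(ctor)))])
  run_config(
    synth = listify(synth_config, x$synth),
    net = listify(net_config, x$net),
    train = listify(train_config, x$train),
    phaser = listify(phaser_options, x$phaser),
    seed = x$seed)
}
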