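# Mesh, configuration and checkpoint I/O.  Meshes travel as ASCII OFF/PLY;
# observables and event logs as delimited text; checkpoints as JSON.

#' Write a mesh to an ASCII OFF or PLY file
#'
#' @param mesh a [trimesh].
#' @param path output file.
#' @param format \code{"off"} or \code{"ply"}; inferred from the extension
#'   when missing.
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  format <- infer_format(path, format)
  p <- mesh$positions
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  pos_lines <- sprintf("%.17g %.17g %.17g", p[, 1], p[, 2], p[, 3])
  face_lines <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  if (format == "off") {
    writeLines(c("OFF",
                 sprintf("%d %d %d", nrow(p), nrow(f), 0L),
                 pos_lines, face_lines), con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(p)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header", pos_lines, face_lines), con)
  }
  invisible(path)
}

#' Read a mesh from an ASCII OFF or PLY file
#'
#' @param path input file.
#' @param format \code{"off"} or \code{"ply"}; inferred from the extension.
#' @param closed validate as a closed mesh (default) or allow boundaries.
#' @return A [trimesh].  Malformed files raise a parse error naming the line.
#' @export
read_mesh <- function(path, format = NULL, closed = TRUE) {
  format <- infer_format(path, format)
  lines <- readLines(path, warn = FALSE)
  parse_fail <- function(lineno, what) {
    stop(errorCondition(
      sprintf("%s:%d: %s", basename(path), lineno, what),
      class = c("dtv_parse_error", "error", "condition")))
  }
  fields <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  if (format == "off") {
    if (length(lines) < 2 || toupper(trimws(lines[1])) != "OFF")
      parse_fail(1, "expected OFF header")
    i <- 2
    while (i <= length(lines) &&
           (trimws(lines[i]) == "" || startsWith(trimws(lines[i]), "#")))
      i <- i + 1
    cnt <- suppressWarnings(as.integer(fields(i)))
    if (length(cnt) < 2 || anyNA(cnt[1:2]))
      parse_fail(i, "expected 'V F E' counts")
    nv <- cnt[1]; nf <- cnt[2]
    vstart <- i + 1
  } else {
    if (length(lines) < 3 || trimws(lines[1]) != "ply")
      parse_fail(1, "expected 'ply' magic")
    endh <- which(trimws(lines) == "end_header")[1]
    if (is.na(endh)) parse_fail(length(lines), "missing end_header")
    nv <- nf <- NA_integer_
    for (i in seq_len(endh)) {
      fl <- fields(i)
      if (length(fl) == 3 && fl[1] == "element") {
        if (fl[2] == "vertex") nv <- as.integer(fl[3])
        if (fl[2] == "face") nf <- as.integer(fl[3])
      }
    }
    if (is.na(nv) || is.na(nf)) parse_fail(endh, "missing element counts")
    vstart <- endh + 1
  }
  if (vstart + nv + nf - 1 > length(lines))
    parse_fail(length(lines), "file truncated")
  p <- matrix(0, nv, 3)
  for (k in seq_len(nv)) {
    xyz <- suppressWarnings(as.numeric(fields(vstart + k - 1)))
    if (length(xyz) < 3 || anyNA(xyz[1:3]))
      parse_fail(vstart + k - 1, "expected 3 vertex coordinates")
    p[k, ] <- xyz[1:3]
  }
  f <- matrix(0L, nf, 3)
  for (k in seq_len(nf)) {
    ln <- vstart + nv + k - 1
    idx <- suppressWarnings(as.integer(fields(ln)))
    if (length(idx) < 4 || anyNA(idx[1:4]) || idx[1] != 3L)
      parse_fail(ln, "expected a triangle face '3 i j k'")
    f[k, ] <- idx[2:4] + 1L
  }
  trimesh(p, f, closed = closed)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("off", "ply")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("off", "ply")) ext else "off"
}

#' Read / write a flat key-value run configuration
#'
#' The configuration file is flat YAML whose keys are the model's standard
#' symbol names (\code{K_v}, \code{K_a}, \code{K_c}, \code{kappa_act},
#' \code{v_eq}, \code{a_eq}, \code{K_r}, \code{l_rep}, \code{eta},
#' \code{k_BT}, \code{tau_f}, \code{tau_t}, \code{eps_t}, \code{gamma_t},
#' \code{M_eq}, \code{M_inst}, \code{m_u}, \code{M_tt}) plus the run schedule
#' (\code{dt}, \code{t_end}, \code{sample_every}, \code{seed}, \code{faces},
#' \code{sphericity}).  \code{tau_t: .inf} disables turnover.
#' Parse, serialize, parse is the identity.
#'
#' @param path file path.
#' @return \code{read_config}: a [sim_config] with attribute \code{"extra"}
#'   holding \code{faces} and \code{sphericity}.
#' @export
read_config <- function(path) {
  kv <- yaml::read_yaml(path)
  config_from_keys(kv)
}

config_from_keys <- function(kv) {
  pick <- function(name, default) if (!is.null(kv[[name]])) kv[[name]] else default
  mp <- mech_params(
    K_v = pick("K_v", 1e4), K_a = pick("K_a", 50), K_c = pick("K_c", 10),
    a_eq = pick("a_eq", 1),
    v_eq = pick("v_eq", equilibrium_volume(pick("faces", 1000),
                                           pick("sphericity", 0.85))),
    K_r = pick("K_r", 1e3),
    l_rep = pick("l_rep", 0.5 * sqrt(4 * pick("a_eq", 1) / sqrt(3))),
    kappa_act = pick("kappa_act", 0), eta = pick("eta", 10),
    k_BT = pick("k_BT", 1))
  tp <- turnover_params(tau_f = pick("tau_f", 1e-2),
                        tau_t = pick("tau_t", 1),
                        eps_t = pick("eps_t", 0.1),
                        gamma_t = pick("gamma_t", 0.05))
  M_eq <- pick("M_eq", 1e3)
  rs <- reservoir_state(M_eq = M_eq, M_inst = pick("M_inst", 1e3),
                        m_u = pick("m_u", 1), M_tt = pick("M_tt", 2 * M_eq))
  cfg <- sim_config(mech = mp, turnover = tp, reservoir = rs,
                    dt = pick("dt", 1e-3), t_end = pick("t_end", 1),
                    sample_every = pick("sample_every", 100),
                    seed = pick("seed", 1))
  attr(cfg, "extra") <- list(faces = pick("faces", 1000),
                             sphericity = pick("sphericity", 0.85))
  cfg
}

#' @rdname read_config
#' @param config a [sim_config].
#' @export
write_config <- function(config, path) {
  ex <- attr(config, "extra")
  kv <- c(unclass(config$mech),
          unclass(config$turnover),
          config$reservoir[c("M_eq", "M_inst", "m_u", "M_tt")],
          list(dt = config$dt, t_end = config$t_end,
               sample_every = config$sample_every, seed = config$seed),
          if (!is.null(ex)) ex)
  yaml::write_yaml(kv, path, precision = 15)
  invisible(path)
}

#' Write / read simulation checkpoints
#'
#' A checkpoint bundles the vertex positions, faces, reservoir integers, run
#' counters and R's RNG state as JSON; positions are stored to 16
#' significant digits.
#'
#' @param sim a \code{dtv_sim} object from [run_simulation()].
#' @param path file path.
#' @export
write_checkpoint <- function(sim, path) {
  ck <- list(positions = sim$mesh$positions, faces = sim$mesh$faces,
             reservoir = unclass(sim$reservoir), state = sim$state,
             rng = get(".Random.seed", envir = globalenv()))
  jsonlite::write_json(ck, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- lapply(ck$reservoir, as.numeric)
  list(mesh = trimesh(ck$positions, ck$faces),
       reservoir = structure(res, class = "reservoir_state"),
       state = lapply(ck$state, as.numeric), rng = as.integer(ck$rng))
}

#' Write observables / event logs as delimited text
#'
#' @param x data frame (observables or events).
#' @param path output file (tab-separated, one header row).
#' @export
write_table_log <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
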