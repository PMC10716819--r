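#' Parse a G-code document into a toolpath
#'
#' Supports the linear-move dialect used by the printer controller: `G0`
#' (travel) and `G1` (print) with absolute `X`/`Y`/`Z` coordinates (mm), `F`
#' feed words (mm/min on the wire, stored as mm/s), optional `E` extrusion
#' words, `;` comments, `G21`/`G90` mode lines, and the custom `M102 P<code>`
#' LED command. An `M102` line is preserved as an annotation on the move that
#' follows it (column `m102` of the move table), so a parse/emit cycle
#' round-trips the LED schedule.
#'
#' The machine is pneumatic-extrusion: most print moves carry no `E` word, so
#' a `G1` motion is a print move unless it carries an `E` word that does not
#' increase the extruder position. Arcs (`G2`/`G3`) and relative mode (`G91`)
#' are rejected with an error naming the offending line.
#'
#' @param text G-code document: a single string or a character vector of lines.
#' @param layer_thickness Layer thickness (mm) recorded on the toolpath.
#' @return A `toolpath`.
#' @export
parse_gcode <- function(text, layer_thickness = 0.2) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    strsplit(text, "\n", fixed = TRUE)[[1]] else as.character(text)
  pos <- c(x = 0, y = 0, z = 0)
  feed <- NA_real_   # mm/s
  e_pos <- 0
  pending_m102 <- NA_integer_
  rows <- vector("list", length(lines))
  nrows <- 0L
  lt <- layer_thickness
  for (i in seq_along(lines)) {
    raw <- lines[i]
    code <- sub(";.*$", "", raw)
    code <- trimws(code)
    if (!nzchar(code)) {
      cm <- regmatches(raw, regexec(";\\s*layer_thickness\\s*=\\s*([0-9.]+)", raw))[[1]]
      if (length(cm) == 2L) lt <- as.numeric(cm[2])
      next
    }
    words <- parse_words(code, i)
    letters_ <- names(words)
    if ("G" %in% letters_) {
      g <- words[["G"]]
      if (g %in% c(2, 3))
        stop("line ", i, ": arc motion G", g, " is not supported (linear moves only)")
      if (g == 91)
        stop("line ", i, ": relative positioning (G91) is not supported; absolute (G90) only")
      if (!(g %in% c(0, 1, 21, 90)))
        stop("line ", i, ": unsupported G word G", g)
      if (g %in% c(21, 90)) next
      new <- pos
      if ("X" %in% letters_) new["x"] <- words[["X"]]
      if ("Y" %in% letters_) new["y"] <- words[["Y"]]
      if ("Z" %in% letters_) new["z"] <- words[["Z"]]
      if ("F" %in% letters_) feed <- words[["F"]] / 60  # mm/min -> mm/s
      de <- 0
      if ("E" %in% letters_) { de <- words[["E"]] - e_pos; e_pos <- words[["E"]] }
      if (max(abs(new - pos)) > 1e-12) {
        kind <- if (g == 0) "travel"
                else if ("E" %in% letters_ && de <= 0) "travel" else "print"
        nrows <- nrows + 1L
        rows[[nrows]] <- data.frame(
          kind = kind, x0 = unname(pos["x"]), y0 = unname(pos["y"]),
          z0 = unname(pos["z"]), x1 = unname(new["x"]), y1 = unname(new["y"]),
          z1 = unname(new["z"]), feed = feed, m102 = pending_m102)
        pending_m102 <- NA_integer_
        pos <- new
      }
    } else if ("M" %in% letters_) {
      if (words[["M"]] == 102) {
        if (!("P" %in% letters_))
          stop("line ", i, ": M102 requires a P<code> word")
        p <- words[["P"]]
        if (p != round(p) || p < 0 || p > 9)
          stop("line ", i, ": M102 code must be an integer in 0..9, got ", p)
        pending_m102 <- as.integer(p)
      }
      # other M words (M3, M84, ...) carry no motion; ignored
    } else {
      stop("line ", i, ": unrecognized command '", code, "'")
    }
  }
  moves <- if (nrows > 0L) do.call(rbind, rows[seq_len(nrows)]) else
    data.frame(kind = character(), x0 = numeric(), y0 = numeric(),
               z0 = numeric(), x1 = numeric(), y1 = numeric(), z1 = numeric(),
               feed = numeric(), m102 = integer())
  rownames(moves) <- NULL
  toolpath(moves, layer_thickness = lt, meta = list(source = "gcode"))
}

# split a G-code line into named letter->number words
parse_words <- function(code, lineno) {
  toks <- regmatches(code, gregexpr("[A-Za-z][-+]?[0-9]*\\.?[0-9]+", code))[[1]]
  if (length(toks) == 0L)
    stop("line ", lineno, ": cannot parse '", code, "'")
  vals <- as.numeric(substring(toks, 2))
  names(vals) <- toupper(substring(toks, 1, 1))
  vals
}

#' Serialize a toolpath to G-code with injected LED commands
#'
#' Emits `G21`/`G90` preamble, `G0`/`G1` motion lines with fixed 3-decimal
#' coordinate formatting, modal `F` words (mm/min), and one `M102 P<code>`
#' line immediately before each addressed move. Consecutive duplicate LED
#' codes are suppressed: the device keeps its last state, so repeating the
#' command is redundant.
#'
#' @param path A `toolpath`.
#' @param commands data.frame with columns `move` (1-based move index) and
#'   `code` (integer 0..9; 0 = all off, 9 = all on), or `NULL` to use the
#'   `m102` annotations already present on the path (e.g. from [parse_gcode()]).
#' @param trailing_off If `TRUE`, append a final `M102 P0` switching every LED
#'   off after the last move.
#' @return Character vector of G-code lines.
#' @export
emit_gcode <- function(path, commands = NULL, trailing_off = FALSE) {
  stopifnot(inherits(path, "toolpath"))
  m <- path$moves
  if (is.null(commands)) {
    idx <- which(!is.na(m$m102))
    commands <- data.frame(move = idx, code = m$m102[idx])
  }
  if (nrow(commands) > 0L) {
    if (!all(c("move", "code") %in% names(commands)))
      stop("commands must have columns 'move' and 'code'")
    if (any(commands$move < 1 | commands$move > nrow(m)))
      stop("command addresses a move outside the path")
    if (any(commands$code != round(commands$code) |
            commands$code < 0 | commands$code > 9))
      stop("LED codes must be integers in 0..9 (0 = off, 1..8 = couples, 9 = all on)")
    commands <- commands[order(commands$move), , drop = FALSE]
  }
  code_for <- rep(NA_integer_, nrow(m))
  code_for[commands$move] <- as.integer(commands$code)
  out <- c(sprintf("; photopath toolpath | layer_thickness=%.3f", path$layer_thickness),
           "G21 ; units mm", "G90 ; absolute positioning")
  last_code <- NA_integer_
  last_feed <- NA_real_
  if (nrow(m) > 0L && max(abs(c(m$x0[1], m$y0[1], m$z0[1]))) > 1e-9)
    out <- c(out, sprintf("G0 X%.3f Y%.3f Z%.3f", m$x0[1], m$y0[1], m$z0[1]))
  for (i in seq_len(nrow(m))) {
    ci <- code_for[i]
    if (!is.na(ci) && (is.na(last_code) || ci != last_code)) {
      out <- c(out, sprintf("M102 P%d", ci))
      last_code <- ci
    }
    word <- if (m$kind[i] == "print") "G1" else "G0"
    line <- sprintf("%s X%.3f Y%.3f Z%.3f", word, m$x1[i], m$y1[i], m$z1[i])
    fi <- m$feed[i]
    if (!is.na(fi) && (is.na(last_feed) || abs(fi - last_feed) > 1e-12)) {
      line <- sprintf("%s F%s", line, format(fi * 60, trim = TRUE))
      last_feed <- fi
    }
    out <- c(out, line)
  }
  if (trailing_off && (is.na(last_code) || last_code != 0L))
    out <- c(out, "M102 P0")
  out
}
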