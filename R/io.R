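#' Read and write time-activity curves as CSV
#'
#' The on-disk format has one row per frame and the header
#' `frame_start_s, frame_end_s, mid_time_min, conc_kBq_per_mL`.
#'
#' @param path File path.
#' @return `read_tac_csv` returns a [tac]; `write_tac_csv` returns `path`
#'   invisibly.
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("frame_start_s", "frame_end_s", "mid_time_min",
            "conc_kBq_per_mL")
  if (!all(need %in% names(df)))
    stop("TAC CSV must have columns: ", paste(need, collapse = ", "))
  sched <- frame_schedule(df$frame_end_s - df$frame_start_s)
  if (max(abs(sched$start_s - df$frame_start_s)) > 1e-6)
    stop("frames must be contiguous and start at 0")
  if (max(abs(sched$mid_min - df$mid_time_min)) > 1e-6)
    stop("mid_time_min inconsistent with frame start/end")
  tac(sched, df$conc_kBq_per_mL)
}

#' @rdname read_tac_csv
#' @param x A [tac].
#' @export
write_tac_csv <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read an input-function specification from JSON
#'
#' Accepts either `{"model": "feng", "params": [A1, A2, A3, l1, l2, l3]}`
#' or `{"model": "tabulated", "t_min": [...], "cp": [...]}`, with an
#' optional `plasma_to_blood_ratio` field.
#'
#' @param path Path to the JSON file.
#' @return A [plasma_input].
#' @export
read_input_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  ratio <- if (!is.null(spec$plasma_to_blood_ratio))
    spec$plasma_to_blood_ratio else 1
  if (identical(spec$model, "feng")) {
    p <- as.numeric(spec$params)
    if (length(p) != 6L) stop("feng model needs 6 params: A1,A2,A3,l1,l2,l3")
    feng_input(A1 = p[1], A2 = p[2], A3 = p[3],
               lambda1 = p[4], lambda2 = p[5], lambda3 = p[6],
               plasma_to_blood_ratio = ratio)
  } else if (identical(spec$model, "tabulated")) {
    tabulated_input(as.numeric(spec$t_min), as.numeric(spec$cp),
                    plasma_to_blood_ratio = ratio)
  } else {
    stop("unknown input-function model: ", spec$model)
  }
}
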