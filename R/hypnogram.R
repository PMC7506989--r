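# Hypnogram reading/writing and sleep-stage label schemes.

.RK_STAGES <- c("Awa", "REM", "S1", "S2", "S3", "S4")
.AASM_STAGES <- c("Awa", "REM", "N1", "N2", "N3")

# codes that mark an epoch as unscorable rather than being a stage
.EXCLUDED_CODES <- c("9", "8", "M", "MT", "?", "X", "-", "-1", "6", "7")

#' Hypnogram: one expert stage label per scored epoch
#'
#' @param labels character vector of raw stage labels; each must belong to
#'   the standard's alphabet (`Awa`, `REM`, `S1`..`S4` for R&K; `Awa`,
#'   `REM`, `N1`..`N3` for AASM) or be the literal `"excluded"` for
#'   movement/unknown epochs.
#' @param epoch_seconds duration of each scored epoch in seconds.
#' @param standard `"R&K"` or `"AASM"`.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_seconds, standard = c("R&K", "AASM")) {
  standard <- match.arg(standard)
  alphabet <- c(if (standard == "R&K") .RK_STAGES else .AASM_STAGES, "excluded")
  bad <- setdiff(unique(labels), alphabet)
  if (length(bad) > 0)
    stop("labels outside the ", standard, " alphabet: ", paste(bad, collapse = ", "))
  if (length(labels) == 0) stop("hypnogram has zero labels")
  structure(list(labels = as.character(labels), epoch_seconds = epoch_seconds,
                 standard = standard),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %gs (%s): %s\n", length(x$labels),
              x$epoch_seconds, x$standard,
              paste(utils::head(x$labels, 8), collapse = " ")))
  invisible(x)
}

.decode_stage <- function(code, standard, dialect, line) {
  code <- trimws(code)
  if (dialect == "dreams_txt") {
    map <- c(W = "Awa", AWA = "Awa", R = "REM", REM = "REM")
    if (code %in% names(map)) return(unname(map[code]))
    if (code %in% c("1", "2", "3", "4")) {
      if (standard == "AASM" && code == "4")
        stop("stage code '4' is not valid under AASM (line ", line, ")")
      return(paste0(if (standard == "R&K") "S" else "N", code))
    }
  } else if (dialect == "isruc_txt") {
    map <- c("0" = "Awa", "1" = "N1", "2" = "N2", "3" = "N3", "5" = "REM")
    if (standard == "R&K")
      map <- c("0" = "Awa", "1" = "S1", "2" = "S2", "3" = "S3", "4" = "S4", "5" = "REM")
    if (code %in% names(map)) return(unname(map[code]))
  }
  if (code %in% .EXCLUDED_CODES) return("excluded")
  stop("unknown stage code '", code, "' at line ", line, " (dialect ", dialect, ")")
}

.decode_edfplus_stage <- function(ann, standard) {
  a <- trimws(ann)
  if (a %in% c("Sleep stage W", "Sleep stage Awa")) return("Awa")
  if (a %in% c("Sleep stage R", "Sleep stage REM")) return("REM")
  m <- regmatches(a, regexec("^Sleep stage ([1-4])$", a))[[1]]
  if (length(m) == 2) {
    if (standard == "AASM")
      return(if (m[2] == "4") "N3" else paste0("N", m[2]))
    return(paste0("S", m[2]))
  }
  m <- regmatches(a, regexec("^Sleep stage N([1-3])$", a))[[1]]
  if (length(m) == 2)
    return(if (standard == "R&K") paste0("S", m[2]) else paste0("N", m[2]))
  if (grepl("^Sleep stage", a) || a %in% c("Movement time", "Sleep stage ?"))
    return("excluded")
  NA_character_  # not a sleep-stage event at all
}

#' Load a hypnogram file
#'
#' Supported dialects:
#' \describe{
#'   \item{`dreams_txt`}{one stage code per line (`W`, `R`, `1`..`4`);
#'     unknown-epoch codes such as `9` or `M` become `"excluded"`.}
#'   \item{`isruc_txt`}{one numeric code per line (`0`=wake, `1`..`3`=N1..N3,
#'     `5`=REM).}
#'   \item{`edfplus`}{`Sleep stage ...` events on the EDF+ annotation track,
#'     expanded to one label per `epoch_seconds`.}
#' }
#' Excluded (movement/unknown) epochs are preserved as `"excluded"`, never
#' silently dropped.
#'
#' @param path hypnogram file.
#' @param dialect one of `"edfplus"`, `"dreams_txt"`, `"isruc_txt"`.
#' @param epoch_seconds scoring epoch length in seconds.
#' @param standard `"R&K"` or `"AASM"`; defaults to `"R&K"` for
#'   `dreams_txt`/`edfplus` and `"AASM"` for `isruc_txt`.
#' @return A [hypnogram].
#' @export
load_hypnogram <- function(path, dialect = c("edfplus", "dreams_txt", "isruc_txt"),
                           epoch_seconds = 30, standard = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(standard))
    standard <- if (dialect == "isruc_txt") "AASM" else "R&K"
  if (dialect == "edfplus") {
    tals <- .read_edfplus_events(path)
    labels <- character(0)
    for (tal in tals) {
      for (a in tal$labels) {
        st <- .decode_edfplus_stage(a, standard)
        if (is.na(st)) next
        dur <- if (is.finite(tal$duration)) tal$duration else epoch_seconds
        n <- max(1L, as.integer(round(dur / epoch_seconds)))
        k <- as.integer(round(tal$onset / epoch_seconds))
        labels[(k + 1):(k + n)] <- st
      }
    }
    labels[is.na(labels) | labels == ""] <- "excluded"
    if (length(labels) == 0) stop("no sleep-stage events found in ", path)
    return(hypnogram(labels, epoch_seconds, standard))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("hypnogram file has zero labels: ", path)
  codes <- unlist(lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[i]), "[,;[:space:]]+")[[1]]
    stats::setNames(toks, rep(i, length(toks)))
  }))
  labels <- vapply(seq_along(codes),
                   function(i) .decode_stage(codes[i], standard, dialect,
                                             names(codes)[i]),
                   "")
  hypnogram(labels, epoch_seconds, standard)
}

#' Write a hypnogram in one of the supported dialects
#'
#' The inverse of [load_hypnogram]; round-trips label sequences exactly.
#'
#' @param hyp a [hypnogram].
#' @param path output path.
#' @param dialect output dialect (see [load_hypnogram]).
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path,
                            dialect = c("dreams_txt", "isruc_txt", "edfplus")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(hyp, "hypnogram"))
  if (dialect == "dreams_txt") {
    enc <- c(Awa = "W", REM = "R", S1 = "1", S2 = "2", S3 = "3", S4 = "4",
             N1 = "1", N2 = "2", N3 = "3", excluded = "9")
    writeLines(unname(enc[hyp$labels]), path)
  } else if (dialect == "isruc_txt") {
    enc <- c(Awa = "0", REM = "5", S1 = "1", S2 = "2", S3 = "3", S4 = "4",
             N1 = "1", N2 = "2", N3 = "3", excluded = "9")
    writeLines(unname(enc[hyp$labels]), path)
  } else {
    enc <- c(Awa = "Sleep stage W", REM = "Sleep stage R",
             S1 = "Sleep stage 1", S2 = "Sleep stage 2",
             S3 = "Sleep stage 3", S4 = "Sleep stage 4",
             N1 = "Sleep stage N1", N2 = "Sleep stage N2",
             N3 = "Sleep stage N3", excluded = "Sleep stage ?")
    es <- hyp$epoch_seconds
    tals <- lapply(seq_along(hyp$labels), function(k) {
      onset <- (k - 1) * es
      c(charToRaw(sprintf("+%g\x14\x14", onset)), as.raw(0),
        charToRaw(sprintf("+%g\x15%g\x14%s\x14", onset, es,
                          enc[hyp$labels[k]])), as.raw(0))
    })
    .write_edf(NULL, NA, NULL, path, record_seconds = es,
               annotations = tals, ann_only = TRUE)
  }
  invisible(path)
}

#' Sleep-stage label scheme
#'
#' Builds the stage-merging map for the 2- to 6-class (R&K) or 2- to
#' 5-class (AASM) classification schemes.  Class indices start at 0 in the
#' stage order Awa, REM, then ascending sleep depth; e.g. R&K 4-class
#' merges S1 with S2 and S3 with S4.
#'
#' @param standard `"R&K"` or `"AASM"`.
#' @param n_classes number of classes (2..6 for R&K, 2..5 for AASM).
#' @return An object of class `label_scheme` with fields `standard`,
#'   `n_classes`, `mapping` (named integer vector, stage -> 0-based class)
#'   and `class_names`.
#' @export
label_scheme <- function(standard = c("R&K", "AASM"), n_classes) {
  standard <- match.arg(standard)
  stages <- if (standard == "R&K") .RK_STAGES else .AASM_STAGES
  maxc <- length(stages)
  if (!(n_classes %in% 2:maxc))
    stop("n_classes must be in 2..", maxc, " for ", standard)
  groups <- if (standard == "R&K") {
    switch(as.character(n_classes),
      "6" = list("Awa", "REM", "S1", "S2", "S3", "S4"),
      "5" = list("Awa", "REM", "S1", "S2", c("S3", "S4")),
      "4" = list("Awa", "REM", c("S1", "S2"), c("S3", "S4")),
      "3" = list("Awa", "REM", c("S1", "S2", "S3", "S4")),
      "2" = list("Awa", c("REM", "S1", "S2", "S3", "S4")))
  } else {
    switch(as.character(n_classes),
      "5" = list("Awa", "REM", "N1", "N2", "N3"),
      "4" = list("Awa", "REM", c("N1", "N2"), "N3"),
      "3" = list("Awa", "REM", c("N1", "N2", "N3")),
      "2" = list("Awa", c("REM", "N1", "N2", "N3")))
  }
  mapping <- integer(0)
  for (g in seq_along(groups))
    mapping[groups[[g]]] <- g - 1L
  nm <- vapply(groups, function(g) {
    if (length(g) == 1) g
    else if (identical(sort(g), sort(setdiff(stages, c("Awa", "REM"))))) "NREM"
    else if (identical(sort(g), sort(setdiff(stages, "Awa")))) "Asleep"
    else paste(g, collapse = "+")
  }, "")
  structure(list(standard = standard, n_classes = as.integer(n_classes),
                 mapping = mapping, class_names = nm),
            class = "label_scheme")
}

#' Map raw hypnogram labels to scheme class indices
#'
#' Excluded epochs are masked out (reported via the keep-mask), not merged
#' into any class.
#'
#' @param hyp a [hypnogram].
#' @param scheme a [label_scheme] with the same scoring standard.
#' @return A list with `classes` (0-based class index for each kept epoch),
#'   `keep` (logical mask over all hypnogram epochs) and `class_names`.
#' @export
map_labels <- function(hyp, scheme) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(scheme, "label_scheme"))
  if (hyp$standard != scheme$standard)
    stop("hypnogram standard (", hyp$standard, ") does not match scheme (",
         scheme$standard, ")")
  keep <- hyp$labels != "excluded"
  classes <- unname(scheme$mapping[hyp$labels[keep]])
  list(classes = as.integer(classes), keep = keep,
       class_names = scheme$class_names)
}
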