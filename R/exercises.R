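#' Build an exercise set from a folder hierarchy
#'
#' Walks `root` depth-first: any folder containing at least one JCAMP-DX
#' file (`.jdx`/`.dx`) and exactly one molfile is a leaf exercise;
#' intermediate folders become categories of the table of contents.
#' Ordering is deterministic (lexicographic), so re-running produces
#' byte-identical `toc.json` (written at the root) and per-leaf
#' `exercise.json` files.  The shown molecular formula is computed from
#' the solution molfile; the solution structure itself never enters the
#' JSON outputs.
#'
#' @param root exercise tree root.
#' @param write_json write `toc.json` / `exercise.json` files (default TRUE).
#' @return object of class `exercise_set`: `toc` (nested categories) and
#'   `exercises` (list of exercises with `id`, `spectra`, `solution`
#'   molecule, `shown_formula`, `difficulty`).
#' @export
build_toc <- function(root, write_json = TRUE) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  exercises <- list()
  walk <- function(dir, rel) {
    entries <- sort(list.files(dir), method = "radix")
    full <- file.path(dir, entries)
    jdx <- entries[grepl("\\.(jdx|dx)$", entries, ignore.case = TRUE) &
                     !dir.exists(full)]
    mol <- entries[grepl("\\.mol$", entries, ignore.case = TRUE) &
                     !dir.exists(full)]
    subdirs <- entries[dir.exists(full)]
    if (length(jdx) > 0 || length(mol) > 0) {
      if (length(mol) != 1)
        stop(sprintf("exercise folder '%s' must contain exactly one molfile (found %d)",
                     dir, length(mol)))
      if (length(jdx) < 1)
        stop(sprintf("exercise folder '%s' has a molfile but no JCAMP-DX spectra", dir))
      sol <- parse_molfile(file.path(dir, mol))
      difficulty <- NULL
      meta <- file.path(dir, "meta.json")
      if (file.exists(meta)) {
        md <- jsonlite::fromJSON(meta, simplifyVector = FALSE)
        difficulty <- md$difficulty
      }
      ex <- list(id = rel,
                 spectra = file.path(rel, jdx),
                 solution = sol,
                 shown_formula = molecular_formula(sol),
                 difficulty = difficulty)
      exercises[[length(exercises) + 1L]] <<- ex
      if (write_json) {
        doc <- list(id = ex$id, spectra = as.list(jdx),
                    formula = ex$shown_formula)
        if (!is.null(difficulty)) doc$difficulty <- difficulty
        writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE),
                   file.path(dir, "exercise.json"), useBytes = TRUE)
      }
      return(list(kind = "exercise", id = rel, formula = ex$shown_formula))
    }
    children <- list()
    for (sd in subdirs) {
      child <- walk(file.path(dir, sd),
                    if (nzchar(rel)) paste(rel, sd, sep = "/") else sd)
      if (!is.null(child)) children[[length(children) + 1L]] <- child
    }
    if (length(children) == 0) return(NULL)
    list(kind = "category", name = if (nzchar(rel)) basename(rel) else ".",
         children = children)
  }
  toc <- walk(normalizePath(root), "")
  if (is.null(toc)) stop("no exercises found under ", root)
  if (write_json)
    writeLines(jsonlite::toJSON(toc, auto_unbox = TRUE, pretty = TRUE),
               file.path(root, "toc.json"), useBytes = TRUE)
  structure(list(toc = toc, exercises = exercises, root = normalizePath(root)),
            class = "exercise_set")
}

#' Grade a student answer against an exercise
#'
#' Delegates to [check_answer()]; the verdict payload reports only the
#' verdict code and whether the molecular formula matches — it never
#' contains the solution structure.
#'
#' @param ex one exercise from [build_toc()]`$exercises`.
#' @param candidate a [parse_molfile()] molecule (the student's answer).
#' @param stereo require matching tetrahedral parity (default FALSE).
#' @return list with `verdict` (`"correct"`, `"wrong_constitution"`,
#'   `"wrong_stereo"`) and `formula_match`.
#' @export
grade_exercise <- function(ex, candidate, stereo = FALSE) {
  stopifnot(inherits(candidate, "molecule"))
  verdict <- check_answer(candidate, ex$solution, stereo = stereo)
  list(verdict = verdict,
       formula_match = molecular_formula(candidate) == ex$shown_formula)
}

#' Export a project bundle for an exercise
#'
#' The student bundle carries the spectra and the shown molecular formula
#' but not the solution structure; the instructor bundle additionally
#' embeds the solution molecule.
#'
#' @param ex one exercise from [build_toc()]`$exercises`.
#' @param out output project path.
#' @param root the exercise-set root the spectra paths are relative to.
#' @param instructor include the solution molecule (default FALSE).
#' @return invisibly, `out`.
#' @export
export_student_bundle <- function(ex, out, root, instructor = FALSE) {
  p <- new_project()
  for (sp in ex$spectra) {
    imported <- import_any(file.path(root, sp))
    for (s in imported$spectra)
      p <- project_add_spectrum(p, raw = s$raw, spectrum = s$spectrum)
  }
  if (instructor) p <- project_add_molecule(p, ex$solution)
  p$display$shown_formula <- ex$shown_formula
  p$display$exercise_id <- ex$id
  save_project(p, out)
  invisible(out)
}
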