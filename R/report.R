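# MetricReport aggregation and serialization (JSON / TSV).

.schemaVersion <- "1.0"

#' Compare two ensembles with the full metric battery
#'
#' Runs the requested subset of scores comparing a proposed (generated)
#' ensemble against a reference ensemble and an initial/native structure,
#' and aggregates everything into a serializable \linkS4class{MetricReport}.
#'
#' @param reference reference \linkS4class{Ensemble} (e.g. MD).
#' @param proposed proposed \linkS4class{Ensemble} sharing the topology.
#' @param native natoms x 3 matrix of the initial/native structure; defaults
#'   to the first reference frame.
#' @param metrics character subset of
#'   c("rmsf", "chijsd", "ssep", "fsf", "init_rmsd", "rg", "contact_map",
#'   "integrity", "landscape").
#' @param seed seed recorded in the report metadata (analysis itself is
#'   deterministic).
#' @return a \linkS4class{MetricReport}.
#' @export
compareEnsembles <- function(reference, proposed, native = NULL,
                             metrics = c("rmsf", "chijsd", "ssep", "fsf",
                                         "init_rmsd", "rg", "contact_map",
                                         "integrity"),
                             seed = NA_integer_) {
  if (!identical(reference@topology@resNames, proposed@topology@resNames)) {
    a <- reference@topology@resNames; b <- proposed@topology@resNames
    n <- min(length(a), length(b))
    diffAt <- which(a[seq_len(n)] != b[seq_len(n)])[1]
    stop(sprintf("topology mismatch at residue %s",
                 if (is.na(diffAt)) sprintf("count (%d vs %d)", length(a), length(b))
                 else sprintf("%d (%s vs %s)", diffAt, a[diffAt], b[diffAt])))
  }
  if (is.null(native)) native <- getFrame(reference, 1)
  scalar <- list(); profiles <- list(); histograms <- list(); warn <- character(0)
  grab <- function(expr, what) tryCatch(expr, error = function(e) {
    warn <<- c(warn, sprintf("%s: %s", what, conditionMessage(e)))
    NULL
  })
  if ("rmsf" %in% metrics) {
    ra <- grab(rmsfProfile(reference, native), "rmsf(reference)")
    rb <- grab(rmsfProfile(proposed, native), "rmsf(proposed)")
    if (!is.null(ra) && !is.null(rb)) {
      profiles$rmsf_reference <- ra
      profiles$rmsf_proposed <- rb
      scalar$rmsf_pcc <- grab(rmsfPcc(ra, rb), "rmsf_pcc")
    }
  }
  if ("chijsd" %in% metrics)
    scalar$chijsd <- grab(as.numeric(chiJsd(reference, proposed)), "chijsd")
  if ("ssep" %in% metrics) {
    s <- grab(ssep(proposed, native), "ssep")
    if (!is.null(s)) {
      scalar$ssep <- as.numeric(s)
      profiles$ssep_per_frame <- attr(s, "perFrame")
    }
  }
  if ("fsf" %in% metrics) {
    contacts <- grab(nativeContacts(native, proposed@topology), "native_contacts")
    if (!is.null(contacts) && nrow(contacts@contacts)) {
      fs <- grab(foldedStateFraction(proposed, contacts), "fsf")
      if (!is.null(fs)) {
        scalar$fsf <- as.numeric(fs)
        profiles$q_per_frame <- attr(fs, "q")
      }
    } else warn <- c(warn, "fsf: empty native contact set")
  }
  if ("init_rmsd" %in% metrics) {
    profiles$init_rmsd_per_frame <- initRmsd(proposed, native)
    scalar$mean_init_rmsd <- mean(profiles$init_rmsd_per_frame)
  }
  if ("rg" %in% metrics) {
    profiles$rg_per_frame <- radiusOfGyration(proposed)
    scalar$mean_rg <- mean(profiles$rg_per_frame)
  }
  if ("contact_map" %in% metrics) {
    histograms$contact_map_reference <- contactMap(reference)
    histograms$contact_map_proposed <- contactMap(proposed)
  }
  if ("integrity" %in% metrics) {
    ir <- integrityReport(proposed)
    scalar$mean_clashes <- meanClashes(ir)
    scalar$mean_violations <- meanViolations(ir)
    profiles$clashes_per_frame <- ir@clashesPerFrame
    profiles$violations_per_frame <- ir@violationsPerFrame
  }
  if ("landscape" %in% metrics) {
    lm <- grab(fitLandscape(reference), "landscape")
    if (!is.null(lm)) {
      histograms$landscape_reference <- projectLandscape(lm, reference)
      histograms$landscape_proposed <- projectLandscape(lm, proposed)
    }
  }
  scalar <- Filter(Negate(is.null), scalar)
  bad <- names(scalar)[!vapply(scalar, is.finite, logical(1))]
  for (nm in bad) {
    warn <- c(warn, sprintf("%s: non-finite value set to null", nm))
    scalar[nm] <- list(NULL)
  }
  new("MetricReport",
      meta = list(schema_version = .schemaVersion,
                  package_version = as.character(utils::packageVersion("EnsembleMetrics")),
                  reference = reference@label, proposed = proposed@label,
                  metrics = metrics, seed = seed,
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      scalar = scalar, profiles = profiles, histograms = histograms,
      warnings = warn)
}

#' Serialize a metric report
#'
#' JSON output is the stable nested schema
#' \code{{"meta": ..., "scalar": ..., "profiles": ..., "histograms": ...,
#' "warnings": ...}}; TSV output flattens scalars into a key-value section
#' and per-residue/per-frame profiles into one row per index.
#'
#' @param report a \linkS4class{MetricReport}.
#' @param path output path.
#' @param format "json" or "tsv".
#' @export
writeReport <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(meta = report@meta, scalar = report@scalar,
                profiles = report@profiles, histograms = report@histograms,
                warnings = report@warnings)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", matrix = "rowmajor")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# scalar", con)
    for (nm in names(report@scalar))
      writeLines(sprintf("%s\t%s", nm,
                         format(report@scalar[[nm]], digits = 12)), con)
    for (nm in names(report@profiles)) {
      writeLines(sprintf("# profile\t%s", nm), con)
      v <- report@profiles[[nm]]
      writeLines(sprintf("%d\t%s", seq_along(v), format(v, digits = 12)), con)
    }
  }
  invisible(path)
}
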