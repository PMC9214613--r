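#' Standoff annotation containers
#'
#' An annotated document bundles raw text with entity, trigger and (possibly
#' nested) event annotations in BioNLP-ST standoff semantics: annotations
#' refer to the text by 0-based, end-exclusive character offsets, entities and
#' triggers carry `T`-prefixed ids, events carry `E`-prefixed ids, and an
#' event argument may be filled by an entity or by another event.
#'
#' @param doc_id Document identifier (used as the file stem on disk).
#' @param text Raw document text.
#' @param entities List of [entity_span()] annotations.
#' @param triggers List of [trigger_span()] annotations.
#' @param events List of [event_record()] annotations.
#' @param validate Check invariants on construction (default `TRUE`).
#' @return An object of class `annotated_document`.
#' @seealso [read_standoff()], [write_standoff()], [validate_document()]
#' @export
annotated_document <- function(doc_id, text, entities = list(), triggers = list(),
                               events = list(), validate = TRUE) {
  doc <- structure(
    list(doc_id = doc_id, text = text, entities = entities,
         triggers = triggers, events = events),
    class = "annotated_document"
  )
  if (validate) validate_document(doc)
  doc
}

#' @param id Annotation id (`T`-prefixed for spans, `E`-prefixed for events).
#' @param type Entity or event type label.
#' @param start,end 0-based, end-exclusive character offsets.
#' @param surface Surface string; must equal the `[start, end)` slice of the text.
#' @rdname annotated_document
#' @export
entity_span <- function(id, type, start, end, surface) {
  structure(list(id = id, type = type, start = as.integer(start),
                 end = as.integer(end), surface = surface),
            class = c("entity_span", "standoff_span"))
}

#' @rdname annotated_document
#' @export
trigger_span <- function(id, type, start, end, surface) {
  structure(list(id = id, type = type, start = as.integer(start),
                 end = as.integer(end), surface = surface),
            class = c("trigger_span", "standoff_span"))
}

#' @param trigger_id Id of the trigger span anchoring the event.
#' @param args List of `list(role =, filler_id =)` pairs; a filler id may name
#'   an entity (`T...`) or another event (`E...`), which is how nesting is
#'   represented.
#' @rdname annotated_document
#' @export
event_record <- function(id, trigger_id, args = list()) {
  structure(list(id = id, trigger_id = trigger_id, args = args),
            class = "event_record")
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document '%s': %d chars, %d entities, %d triggers, %d events>\n",
              x$doc_id, nchar(x$text), length(x$entities), length(x$triggers),
              length(x$events)))
  invisible(x)
}

#' Validate an annotated document
#'
#' Checks the standoff invariants: every span's recorded surface equals the
#' corresponding text slice, every event's trigger id resolves to a trigger,
#' every argument filler id resolves to an entity or event of the same
#' document, and the event-to-event reference graph is acyclic (an event can
#' fill another event's role, but no chain of fillers may loop back).
#'
#' @param doc An `annotated_document`.
#' @return The document, invisibly. Throws a classed condition on violation:
#'   `bioevents_offset_mismatch`, `bioevents_dangling_reference` or
#'   `bioevents_cyclic_event`, each naming the offending annotation id.
#' @export
validate_document <- function(doc) {
  n <- nchar(doc$text)
  for (sp in c(doc$entities, doc$triggers)) {
    if (sp$start < 0 || sp$end > n || sp$start >= sp$end) {
      stop_bioevents("bioevents_offset_mismatch",
                     sprintf("span %s has offsets [%d,%d) outside text of length %d",
                             sp$id, sp$start, sp$end, n), id = sp$id)
    }
    got <- slice_text(doc$text, sp$start, sp$end)
    if (!identical(got, sp$surface)) {
      stop_bioevents("bioevents_offset_mismatch",
                     sprintf("span %s surface '%s' != text slice '%s'",
                             sp$id, sp$surface, got), id = sp$id)
    }
  }
  tids <- vapply(doc$triggers, `[[`, "", "id")
  eids <- vapply(doc$entities, `[[`, "", "id")
  vids <- vapply(doc$events, `[[`, "", "id")
  if (anyDuplicated(c(tids, eids)) || anyDuplicated(vids)) {
    stop_bioevents("bioevents_dangling_reference", "duplicate annotation ids")
  }
  for (ev in doc$events) {
    if (!(ev$trigger_id %in% tids)) {
      stop_bioevents("bioevents_dangling_reference",
                     sprintf("event %s trigger id %s does not resolve",
                             ev$id, ev$trigger_id), id = ev$trigger_id)
    }
    for (a in ev$args) {
      if (!(a$filler_id %in% c(tids, eids, vids))) {
        stop_bioevents("bioevents_dangling_reference",
                       sprintf("event %s argument %s does not resolve",
                               ev$id, a$filler_id), id = a$filler_id)
      }
      if (identical(a$filler_id, ev$id)) {
        stop_bioevents("bioevents_cyclic_event",
                       sprintf("event %s fills its own argument slot", ev$id),
                       id = ev$id)
      }
    }
  }
  check_event_acyclic(doc$events)
  invisible(doc)
}

# Depth-first cycle detection over event -> event references.
check_event_acyclic <- function(events) {
  ids <- vapply(events, `[[`, "", "id")
  succ <- lapply(events, function(ev) {
    fl <- vapply(ev$args, `[[`, "", "filler_id")
    fl[fl %in% ids]
  })
  names(succ) <- ids
  state <- setNames(rep(0L, length(ids)), ids)  # 0 unseen, 1 on stack, 2 done
  visit <- function(id) {
    if (state[[id]] == 1L) {
      stop_bioevents("bioevents_cyclic_event",
                     sprintf("event reference cycle through %s", id), id = id)
    }
    if (state[[id]] == 2L) return(invisible(NULL))
    state[[id]] <<- 1L
    for (s in succ[[id]]) visit(s)
    state[[id]] <<- 2L
    invisible(NULL)
  }
  for (id in ids) visit(id)
  invisible(NULL)
}

parse_span_line <- function(line, lineno, ctor) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 3) {
    stop_bioevents("bioevents_parse_error",
                   sprintf("malformed span line %d: '%s'", lineno, line))
  }
  head_bits <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
  if (length(head_bits) != 3) {
    stop_bioevents("bioevents_parse_error",
                   sprintf("malformed span header on line %d", lineno))
  }
  ctor(id = parts[1], type = head_bits[1],
       start = as.integer(head_bits[2]), end = as.integer(head_bits[3]),
       surface = parts[3])
}

parse_event_line <- function(line, lineno) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  bits <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
  anchor <- strsplit(bits[1], ":", fixed = TRUE)[[1]]
  if (length(anchor) != 2) {
    stop_bioevents("bioevents_parse_error",
                   sprintf("malformed event anchor on line %d", lineno))
  }
  args <- lapply(bits[-1], function(b) {
    kv <- strsplit(b, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      stop_bioevents("bioevents_parse_error",
                     sprintf("malformed argument '%s' on line %d", b, lineno))
    }
    list(role = kv[1], filler_id = kv[2])
  })
  event_record(id = parts[1], trigger_id = anchor[2], args = args)
}

#' Read a standoff-annotated document
#'
#' Reads the BioNLP-ST triple: raw text (`.txt`), entity annotations (`.a1`,
#' lines `Tn<TAB>TYPE START END<TAB>SURFACE`) and trigger/event annotations
#' (`.a2`; trigger lines share the entity line format, event lines are
#' `En<TAB>TYPE:Tt ROLE:ID ...`). The `.a2` file may be absent (prediction
#' mode). All invariants are checked, including acyclicity of event
#' references.
#'
#' @param txt_path,a1_path,a2_path File paths; `a2_path` may be `NULL` or a
#'   nonexistent path.
#' @param doc_id Document id; defaults to the `.txt` file stem.
#' @return An [annotated_document()].
#' @export
read_standoff <- function(txt_path, a1_path, a2_path = NULL, doc_id = NULL) {
  text <- paste(readLines(txt_path, warn = FALSE), collapse = "\n")
  a1 <- readLines(a1_path, warn = FALSE)
  a2 <- if (!is.null(a2_path) && file.exists(a2_path)) {
    readLines(a2_path, warn = FALSE)
  } else {
    character()
  }
  doc_id <- doc_id %||% sub("\\.txt$", "", basename(txt_path))
  parse_standoff(text, a1, a2, doc_id)
}

#' @param text,a1_lines,a2_lines In-memory contents (character vector of lines
#'   for the annotation files).
#' @rdname read_standoff
#' @export
parse_standoff <- function(text, a1_lines, a2_lines = character(), doc_id = "doc") {
  a1_lines <- a1_lines[nzchar(a1_lines)]
  a2_lines <- a2_lines[nzchar(a2_lines)]
  entities <- lapply(seq_along(a1_lines), function(i) {
    parse_span_line(a1_lines[i], i, entity_span)
  })
  is_event <- startsWith(a2_lines, "E")
  triggers <- lapply(which(!is_event), function(i) {
    parse_span_line(a2_lines[i], i, trigger_span)
  })
  events <- lapply(which(is_event), function(i) parse_event_line(a2_lines[i], i))
  annotated_document(doc_id, text, entities, triggers, events)
}

format_span_line <- function(sp) {
  sprintf("%s\t%s %d %d\t%s", sp$id, sp$type, sp$start, sp$end, sp$surface)
}

# Events are written in topological order so that any referenced event id
# appears before its use; ties broken by id for byte-deterministic output.
topo_sort_events <- function(events, triggers) {
  ids <- vapply(events, `[[`, "", "id")
  trig_type <- setNames(vapply(triggers, `[[`, "", "type"),
                        vapply(triggers, `[[`, "", "id"))
  done <- character()
  out <- list()
  remaining <- events[order(ids)]
  while (length(remaining) > 0) {
    ready <- vapply(remaining, function(ev) {
      fl <- vapply(ev$args, `[[`, "", "filler_id")
      all(!(fl %in% ids) | fl %in% done)
    }, logical(1))
    if (!any(ready)) {
      stop_bioevents("bioevents_cyclic_event", "event reference cycle on write")
    }
    out <- c(out, remaining[ready])
    done <- c(done, vapply(remaining[ready], `[[`, "", "id"))
    remaining <- remaining[!ready]
  }
  out
}

#' Write a standoff-annotated document
#'
#' Serialises an [annotated_document()] back to the standoff triple. Event
#' lines are topologically sorted so references precede uses, which makes the
#' output deterministic; `read_standoff(write_standoff(doc))` is the identity.
#'
#' @param doc An `annotated_document`.
#' @param dir Optional directory; when given, `<doc_id>.txt/.a1/.a2` are
#'   written there.
#' @return Invisibly, a list with `txt`, `a1` and `a2` character-vector
#'   contents.
#' @export
write_standoff <- function(doc, dir = NULL) {
  validate_document(doc)
  a1 <- vapply(doc$entities, format_span_line, "")
  trig_lines <- vapply(doc$triggers, format_span_line, "")
  trig_type <- setNames(vapply(doc$triggers, `[[`, "", "type"),
                        vapply(doc$triggers, `[[`, "", "id"))
  ev_lines <- vapply(topo_sort_events(doc$events, doc$triggers), function(ev) {
    args <- vapply(ev$args, function(a) paste0(a$role, ":", a$filler_id), "")
    paste0(ev$id, "\t", trig_type[[ev$trigger_id]], ":", ev$trigger_id,
           if (length(args)) paste0(" ", paste(args, collapse = " ")) else "")
  }, "")
  out <- list(txt = doc$text, a1 = a1, a2 = c(trig_lines, ev_lines))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(out$txt, file.path(dir, paste0(doc$doc_id, ".txt")))
    writeLines(out$a1, file.path(dir, paste0(doc$doc_id, ".a1")))
    writeLines(out$a2, file.path(dir, paste0(doc$doc_id, ".a2")))
  }
  invisible(out)
}
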