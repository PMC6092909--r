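#' Build a data request
#'
#' The provider protocol is a JSON envelope: `{request_id, action, params}`
#' in, `{request_id, success, payload|error}` out. Action names and the
#' envelope are artifact-defined (the original wire protocol lives in its
#' implementation, not in print); the columnar payloads follow the
#' `chr`/`start`/`end`/`values` schema.
#'
#' @param request_id Integer id echoed back in the response.
#' @param action One of `"get_measurements"`, `"get_seqinfos"`,
#'   `"get_rows"`, `"get_values"`, `"get_summary"`, `"search_genes"`.
#' @param params Named list of action parameters: `datasource`,
#'   `measurement` (id or vector of ids), `region` (string
#'   `chr:start-end`), `n_bins`, `stat`, `query`.
#' @return An object of class `DataRequest`.
#' @export
data_request <- function(request_id, action, params = list()) {
  actions <- c("get_measurements", "get_seqinfos", "get_rows",
               "get_values", "get_summary", "search_genes")
  if (!action %in% actions) {
    stop("unknown action: ", action, call. = FALSE)
  }
  structure(list(request_id = as.integer(request_id), action = action,
                 params = params),
            class = "DataRequest")
}

response_ok <- function(request_id, payload) {
  list(request_id = request_id, success = TRUE, payload = payload)
}

response_err <- function(request_id, message) {
  list(request_id = request_id, success = FALSE, error = message)
}

find_source <- function(sources, id) {
  for (s in sources) if (s$id == id) return(s)
  NULL
}

measurement_table <- function(src, measurement_id) {
  for (m in src$measurements) {
    if (m$id == measurement_id) return(list(m = m, tab = src$tables[[m$kind]]))
  }
  NULL
}

#' Handle a data request against in-memory datasources
#'
#' The pure core of the provider: no transport involved, so the HTTP layer
#' can be tested for transport transparency against this function.
#' `get_rows`/`get_values` return in-region rows as columnar payloads;
#' `get_summary` returns a binned summary (default 2000 bins, mean);
#' `search_genes` does case-insensitive prefix matching on gene names.
#' Unknown datasources or measurements and malformed regions produce
#' `success = FALSE` with an error message, not an R error.
#'
#' @param request A [data_request()] (or an equivalent plain list parsed
#'   from JSON).
#' @param sources List of [datasource()] objects.
#' @return A response list: `request_id`, `success`, then `payload` or
#'   `error`.
#' @export
handle_request <- function(request, sources) {
  rid <- as.integer(request$request_id %||% -1L)
  action <- request$action
  p <- request$params %||% list()
  tryCatch({
    get_region <- function() {
      if (is.null(p$region)) stop("missing region", call. = FALSE)
      if (inherits(p$region, "GenomicRange")) p$region
      else parse_region(as.character(p$region))
    }
    get_src <- function() {
      src <- find_source(sources, as.character(p$datasource %||% ""))
      if (is.null(src)) {
        stop("unknown datasource: ", p$datasource %||% "<missing>",
             call. = FALSE)
      }
      src
    }
    payload <- switch(action,
      get_seqinfos = {
        src <- get_src()
        list(seqinfo = stats::setNames(as.list(src$seqinfo$length),
                                       src$seqinfo$chrom))
      },
      get_measurements = {
        cat_one <- function(src) lapply(src$measurements, function(m) {
          list(id = m$id, name = m$name, datasource_id = src$id,
               kind = m$kind, value_min = m$value_min, value_max = m$value_max)
        })
        list(measurements = do.call(c, lapply(sources, cat_one)))
      },
      get_rows = ,
      get_values = {
        src <- get_src()
        region <- get_region()
        mids <- as.character(p$measurement %||% character())
        kind <- if (length(mids)) {
          mt <- measurement_table(src, mids[1L])
          if (is.null(mt)) stop("unknown measurement: ", mids[1L], call. = FALSE)
          mt$m$kind
        } else if (length(src$tables)) names(src$tables)[1L] else
          stop("datasource has no tables", call. = FALSE)
        tab <- src$tables[[kind]]
        rows <- rows_in_region(tab, region)
        sub <- subset_rows(tab, rows)
        if (length(mids)) {
          missing_m <- setdiff(mids, names(sub$values))
          if (length(missing_m)) {
            stop("unknown measurement: ", missing_m[1L], call. = FALSE)
          }
          sub$values <- sub$values[mids]
        }
        jsonlite::fromJSON(to_json_columnar(sub), simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
      },
      get_summary = {
        src <- get_src()
        region <- get_region()
        mids <- as.character(p$measurement %||% character())
        kind <- if (length(mids)) {
          mt <- measurement_table(src, mids[1L])
          if (is.null(mt)) stop("unknown measurement: ", mids[1L], call. = FALSE)
          mt$m$kind
        } else if (length(src$tables)) names(src$tables)[1L] else
          stop("datasource has no tables", call. = FALSE)
        tab <- src$tables[[kind]]
        if (length(mids)) {
          keep <- intersect(names(tab$values), mids)
          missing_m <- setdiff(mids, names(tab$values))
          if (length(missing_m)) {
            stop("unknown measurement: ", missing_m[1L], call. = FALSE)
          }
          tab$values <- tab$values[keep]
        }
        bt <- summarize_region(tab, region,
                               n_bins = as.integer(p$n_bins %||% 2000L),
                               stat = as.character(p$stat %||% "mean"))
        jsonlite::fromJSON(binned_to_json(bt), simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
      },
      search_genes = {
        src <- get_src()
        q <- tolower(as.character(p$query %||% ""))
        hits <- Filter(function(g) startsWith(tolower(g$gene_name), q),
                       src$genes)
        list(genes = lapply(hits, function(g) {
          list(gene_name = g$gene_name, chr = g$range$chrom,
               start = g$range$start, end = g$range$end,
               strand = g$strand)
        }))
      },
      stop("unknown action: ", action, call. = FALSE))
    response_ok(rid, payload)
  }, error = function(e) response_err(rid, conditionMessage(e)))
}

response_to_json <- function(resp) {
  as.character(jsonlite::toJSON(resp, null = "null", na = "null",
                                digits = NA, auto_unbox = TRUE))
}

#' Serve datasources over HTTP
#'
#' A small single-threaded HTTP/1.1 endpoint on base-R sockets (no server
#' framework is assumed to be installed): POST a `DataRequest` JSON body to
#' any path and receive the `DataResponse` JSON. Each request is logged
#' with its action and wall time. The handler is stateless; requests are
#' served sequentially in arrival order.
#'
#' @param sources List of [datasource()] objects.
#' @param host Bind address (default 127.0.0.1).
#' @param port TCP port.
#' @param max_requests Stop after this many requests (`Inf` to run until
#'   killed); useful for tests and scripted sessions.
#' @param idle_timeout Seconds without a connection before giving up.
#' @param quiet Suppress the request log.
#' @return Number of requests served, invisibly.
#' @export
serve <- function(sources, host = "127.0.0.1", port = 8877,
                  max_requests = Inf, idle_timeout = 60, quiet = FALSE) {
  srv <- tryCatch(serverSocket(port),
                  error = function(e) stop("cannot bind port ", port, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(srv), add = TRUE)
  if (!quiet) message("listening on ", host, ":", port)
  served <- 0L
  deadline <- Sys.time() + idle_timeout
  while (served < max_requests && Sys.time() < deadline) {
    ready <- socketSelect(list(srv), timeout = 0.25)
    if (!ready) next
    con <- socketAccept(srv, blocking = TRUE, open = "a+b", timeout = 10)
    t0 <- Sys.time()
    req <- tryCatch(read_http_request(con), error = function(e) NULL)
    if (is.null(req)) {
      write_http_response(con, 400, '{"success":false,"error":"bad request"}')
      close(con)
      next
    }
    parsed <- tryCatch(jsonlite::fromJSON(req$body, simplifyVector = TRUE,
                                          simplifyDataFrame = FALSE),
                       error = function(e) NULL)
    if (is.null(parsed) || is.null(parsed$action)) {
      write_http_response(con, 400,
        '{"success":false,"error":"malformed JSON request"}')
    } else {
      resp <- handle_request(parsed, sources)
      write_http_response(con, 200, response_to_json(resp))
      if (!quiet) {
        message(sprintf("%s %s %.1f ms", parsed$action,
                        if (isTRUE(resp$success)) "ok" else "error",
                        as.double(Sys.time() - t0, units = "secs") * 1000))
      }
    }
    close(con)
    served <- served + 1L
    deadline <- Sys.time() + idle_timeout
  }
  invisible(served)
}

read_http_request <- function(con) {
  # request line + headers
  lines <- character()
  repeat {
    l <- readLines(con, n = 1L, warn = FALSE)
    if (!length(l)) stop("connection closed")
    l <- sub("\r$", "", l)
    if (!nzchar(l)) break
    lines <- c(lines, l)
  }
  if (!length(lines)) stop("empty request")
  cl <- grep("^content-length:", lines, ignore.case = TRUE, value = TRUE)
  nbytes <- if (length(cl)) as.integer(trimws(sub("^[^:]+:", "", cl[1]))) else 0L
  body <- if (nbytes > 0L) {
    rawToChar(readBin(con, what = "raw", n = nbytes))
  } else ""
  list(request_line = lines[1L], body = body)
}

write_http_response <- function(con, status, body) {
  msg <- c("HTTP/1.1 ", status, " ",
           if (status == 200) "OK" else "Bad Request", "\r\n",
           "Content-Type: application/json\r\n",
           "Content-Length: ", nchar(body, type = "bytes"), "\r\n",
           "Connection: close\r\n\r\n", body)
  writeBin(charToRaw(paste(msg, collapse = "")), con)
  flush(con)
}

#' POST a data request to a running provider
#'
#' Minimal client on base sockets, mainly for tests and scripting.
#'
#' @param request A [data_request()].
#' @param host,port Provider location.
#' @param timeout Seconds to wait for the response.
#' @return The parsed response list.
#' @export
request_http <- function(request, host = "127.0.0.1", port = 8877,
                         timeout = 10) {
  body <- as.character(jsonlite::toJSON(unclass(request), null = "null",
                                        na = "null", digits = NA,
                                        auto_unbox = TRUE))
  con <- socketConnection(host, port, blocking = TRUE, open = "a+b",
                          timeout = timeout)
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(paste0(
    "POST / HTTP/1.1\r\nHost: ", host,
    "\r\nContent-Type: application/json\r\nContent-Length: ",
    nchar(body, type = "bytes"), "\r\nConnection: close\r\n\r\n", body)), con)
  flush(con)
  status_line <- readLines(con, n = 1L, warn = FALSE)
  nbytes <- 0L
  repeat {
    l <- readLines(con, n = 1L, warn = FALSE)
    if (length(l)) l <- sub("\r$", "", l)
    if (!length(l) || !nzchar(l)) break
    if (grepl("^content-length:", l, ignore.case = TRUE)) {
      nbytes <- as.integer(trimws(sub("^[^:]+:", "", l)))
    }
  }
  raw <- readBin(con, what = "raw", n = nbytes)
  out <- jsonlite::fromJSON(rawToChar(raw), simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  out$http_status <- as.integer(strsplit(status_line, " ")[[1]][2])
  out
}
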