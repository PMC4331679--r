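#' Read and write network files
#'
#' The plain-text network format has two tab-separated sections so that
#' isolated nodes are representable:
#'
#' ```
#' [nodes]
#' name	readout
#' A	0
#' Out	1
#' [edges]
#' source	target	rate
#' A	Out	0.5
#' ```
#'
#' Exactly one node is flagged as the read-out; the `rate` column may be
#' `NA` in a pure-topology file. A `.yaml`/`.yml` path selects an
#' equivalent structured format (`nodes`, `readout`, `edges`). The TSV
#' format round-trips bit-exactly through [save_network()]; YAML carries
#' 15 significant digits. Malformed lines,
#' unknown nodes, duplicate edges and read-out-sink violations raise
#' errors with their location.
#'
#' @param path File path.
#' @return A [signaling_network()]; any rates present are attached as the
#'   `"rates"` attribute (a rate matrix).
#' @export
load_network <- function(path) {
  parsed <- if (grepl("\\.ya?ml$", path)) parse_network_yaml(path)
            else parse_network_tsv(path)
  net <- signaling_network(parsed$nodes, parsed$edges[c("from", "to")],
                           parsed$readout)
  if (nrow(parsed$edges) > 0 && !all(is.na(parsed$edges$rate))) {
    if (anyNA(parsed$edges$rate))
      stop("either all or no edges may carry a rate in ", path)
    attr(net, "rates") <- rate_matrix(parsed$nodes, parsed$edges,
                                      parsed$readout)
  }
  net
}

parse_network_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  i_nodes <- which(lines == "[nodes]")
  i_edges <- which(lines == "[edges]")
  if (length(i_nodes) != 1 || length(i_edges) != 1 || i_edges < i_nodes)
    stop("network file must contain a [nodes] then an [edges] section: ",
         path)
  read_block <- function(block, what) {
    if (length(block) == 0) stop("missing header in ", what, " section")
    con <- textConnection(block)
    on.exit(close(con))
    utils::read.delim(con, stringsAsFactors = FALSE)
  }
  ndf <- read_block(lines[(i_nodes + 1):(i_edges - 1)], "nodes")
  if (!all(c("name", "readout") %in% names(ndf)))
    stop("nodes section needs columns name, readout")
  readout <- ndf$name[ndf$readout == 1]
  if (length(readout) != 1)
    stop("exactly one node must be flagged readout = 1")
  edge_lines <- if (i_edges == length(lines)) character(0)
                else lines[(i_edges + 1):length(lines)]
  if (length(edge_lines) <= 1) {
    edges <- cbind(empty_edge_df(), rate = numeric(0))
  } else {
    edf <- read_block(edge_lines, "edges")
    if (!all(c("source", "target") %in% names(edf)))
      stop("edges section needs columns source, target[, rate]")
    for (col in c("source", "target")) {
      bad <- which(!(edf[[col]] %in% ndf$name))
      if (length(bad) > 0)
        stop("undeclared node '", edf[[col]][bad[1]], "' at edge line ",
             bad[1], " of ", path)
    }
    edges <- data.frame(from = edf$source, to = edf$target,
                        rate = if ("rate" %in% names(edf))
                          as.numeric(edf$rate) else NA_real_,
                        stringsAsFactors = FALSE)
  }
  list(nodes = ndf$name, readout = readout, edges = edges)
}

parse_network_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$nodes), !is.null(y$readout))
  edges <- if (length(y$edges) == 0) cbind(empty_edge_df(), rate = numeric(0))
  else data.frame(
    from = vapply(y$edges, function(e) as.character(e$from), ""),
    to = vapply(y$edges, function(e) as.character(e$to), ""),
    rate = vapply(y$edges, function(e)
      if (is.null(e$rate)) NA_real_ else as.numeric(e$rate), numeric(1)),
    stringsAsFactors = FALSE)
  list(nodes = as.character(y$nodes), readout = as.character(y$readout),
       edges = edges)
}

#' @rdname load_network
#' @param net A [signaling_network()].
#' @param rates Optional rate matrix; when supplied (or attached to `net`)
#'   each edge line carries its rate.
#' @export
save_network <- function(net, path, rates = attr(net, "rates")) {
  ed <- network_edges(net)
  ed$rate <- if (is.null(rates)) NA_real_ else rates[cbind(ed$from, ed$to)]
  if (grepl("\\.ya?ml$", path)) {
    y <- list(nodes = net$node_names, readout = net$readout_node,
              edges = lapply(seq_len(nrow(ed)), function(i) {
                e <- list(from = ed$from[i], to = ed$to[i])
                if (!is.na(ed$rate[i])) e$rate <- ed$rate[i]
                e
              }))
    yaml::write_yaml(y, path, precision = 15)
  } else {
    lines <- c("[nodes]", "name\treadout",
               paste(net$node_names,
                     as.integer(net$node_names == net$readout_node),
                     sep = "\t"),
               "[edges]", "source\ttarget\trate",
               if (nrow(ed) > 0)
                 paste(ed$from, ed$to,
                       ifelse(is.na(ed$rate), "NA",
                              format(ed$rate, digits = 17)), sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read and write rates files
#'
#' A rates file is a network file whose `rate` column is mandatory on
#' every edge; it is loaded into a rate matrix over the file's node set.
#'
#' @param path File path.
#' @return A rate matrix (see [rate_matrix()]) with the node ordering of
#'   the file; its `"readout_node"` attribute names the read-out.
#' @export
load_rates <- function(path) {
  net <- load_network(path)
  rm_ <- attr(net, "rates")
  if (is.null(rm_))
    stop("rates file must provide a rate for every edge: ", path)
  attr(rm_, "readout_node") <- net$readout_node
  rm_
}

#' @rdname load_rates
#' @param node_names,readout_node Node ordering and read-out of the matrix.
#' @param rm A rate matrix.
#' @export
save_rates <- function(rm, node_names, readout_node, path) {
  idx <- which(t(rm) > 0)
  n <- length(node_names)
  k <- idx - 1L
  edges <- data.frame(from = node_names[k %/% n + 1L],
                      to = node_names[k %% n + 1L], stringsAsFactors = FALSE)
  net <- signaling_network(node_names, edges, readout_node)
  save_network(net, path, rates = rm)
}

#' Read and write dataset files
#'
#' Datasets are stored as a single CSV-style text file: a `#meta` line with
#' a JSON metadata block (treatment, time grids, provenance), then a
#' `[signalling]` section (`molecule,t<...>` rows) and a `[phenotype]`
#' section. Round-trips preserve column order and provenance.
#'
#' @param path File path.
#' @return An [experimental_dataset()].
#' @export
load_dataset <- function(path) {
  lines <- readLines(path)
  meta_line <- grep("^#meta ", lines, value = TRUE)
  if (length(meta_line) != 1) stop("dataset file needs one '#meta' line")
  meta <- jsonlite::fromJSON(sub("^#meta ", "", meta_line),
                             simplifyVector = TRUE)
  body <- lines[!grepl("^#", lines)]
  i_sig <- which(body == "[signalling]")
  i_phe <- which(body == "[phenotype]")
  if (length(i_sig) != 1 || length(i_phe) != 1 || i_phe < i_sig)
    stop("dataset file must contain [signalling] then [phenotype] sections")
  read_block <- function(block, n_times, what) {
    con <- textConnection(block)
    on.exit(close(con))
    df <- utils::read.csv(con, stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(df) != n_times + 1)
      stop(what, " section must have ", n_times,
           " value columns, found ", ncol(df) - 1)
    if (nrow(df) == 0)
      return(matrix(numeric(0), 0, n_times,
                    dimnames = list(character(0), NULL)))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                                as.numeric))), arr.ind = TRUE)
      stop("non-numeric value in ", what, " section at row ", bad[1, 1],
           ", column ", bad[1, 2] + 1)
    }
    rownames(m) <- df[[1]]
    m
  }
  sig <- read_block(body[(i_sig + 1):(i_phe - 1)],
                    length(meta$signalling_times), "signalling")
  phe <- read_block(body[(i_phe + 1):length(body)],
                    length(meta$phenotype_times), "phenotype")
  experimental_dataset(
    treatment = meta$treatment, signalling = sig, phenotype = phe,
    signalling_times = meta$signalling_times,
    phenotype_times = meta$phenotype_times,
    readout_node = meta$readout_node,
    provenance = if (is.null(meta$provenance)) list() else meta$provenance)
}

#' @rdname load_dataset
#' @param ds An [experimental_dataset()].
#' @export
save_dataset <- function(ds, path) {
  meta <- jsonlite::toJSON(list(
    treatment = ds$treatment,
    signalling_times = ds$signalling_times,
    phenotype_times = ds$phenotype_times,
    readout_node = ds$readout_node,
    provenance = ds$provenance), auto_unbox = TRUE, digits = NA)
  fmt_block <- function(m, id_col, times) {
    c(paste(c(id_col, paste0("t", times)), collapse = ","),
      vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], format(m[i, ], digits = 17)),
              collapse = ","), character(1)))
  }
  writeLines(c(paste0("#meta ", meta),
               "[signalling]",
               fmt_block(ds$signalling, "molecule", ds$signalling_times),
               "[phenotype]",
               fmt_block(ds$phenotype, "name", ds$phenotype_times)),
             path)
  invisible(path)
}
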