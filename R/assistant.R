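# The task registry and the gather-metrics -> render -> complete -> parse
# loop shared by all ten assistant tasks.

default_method_menu <- c("LogNormalize", "SCTransform", "CLR", "RC")

#' The assistant task registry
#'
#' Binds each of the ten tasks to its metric gatherer, template and parser.
#' Gatherers map a prepared CellDataset (plus options) to the template's
#' placeholder values; parsers map raw response text to the task's payload.
#'
#' @return named list of TaskSpec lists
#' @export
task_registry <- function() {
  reg <- list(
    analyze_quality = list(
      gather = gather_quality, parse = function(text, ctx)
        parse_cutoffs(text, ctx$metric_names)),
    recommend_normalization = list(
      gather = gather_normalization, parse = function(text, ctx)
        list(method = parse_method_choice(text, ctx$method_menu),
             reasoning = text)),
    analyze_variable_features = list(
      gather = gather_variable_features, parse = function(text, ctx)
        list(summary = text)),
    recommend_pcs = list(
      gather = gather_pcs, parse = function(text, ctx)
        list(n_pcs = parse_pc_count(text), reasoning = text)),
    analyze_pcs = list(
      gather = gather_pc_genes, parse = function(text, ctx)
        list(summary = text)),
    recommend_k = list(
      gather = gather_k, parse = function(text, ctx)
        c(parse_k_range(text), list(reasoning = text))),
    recommend_res = list(
      gather = gather_res, parse = function(text, ctx)
        parse_seq_range(text)),
    analyze_and_annotate = list(
      gather = gather_markers, parse = function(text, ctx)
        parse_annotations(text, ctx$clusters)),
    analyze_enrichment = list(
      gather = gather_enrichment, parse = function(text, ctx)
        list(summary = text)),
    summary_network = list(
      gather = gather_network_input, parse = function(text, ctx)
        parse_network_edges(text))
  )
  stopifnot(identical(sort(names(reg)), sort(task_ids())))
  reg
}

# --- per-task metric gatherers -------------------------------------------
# each returns list(values = <placeholder map>, ctx = <parser context>)

gather_quality <- function(ds, opts) {
  metric_names <- opts$metric_names %||%
    intersect(c("total_counts", "n_genes_detected",
                grep("^percent", colnames(ds$cell_meta), value = TRUE)),
              colnames(ds$cell_meta))
  qc <- summarize_qc(ds, metric_names)
  block <- vapply(names(qc$metrics), function(mn) {
    s <- qc$metrics[[mn]]
    paste0(mn, ": mean ", format_full(s$mean), ", median ",
           format_full(s$median), ", sd ", format_full(s$sd),
           ", min ", format_full(s$min), ", max ", format_full(s$max),
           "\n  quantiles: ",
           paste(paste0(names(s$quantiles), "=",
                        format_full(unname(s$quantiles))), collapse = " "))
  }, character(1))
  list(values = list(n_cells = qc$n_cells,
                     qc_stats_block = paste(block, collapse = "\n")),
       ctx = list(metric_names = metric_names))
}

gather_normalization <- function(ds, opts) {
  s <- library_size_stats(ds)
  menu <- opts$method_menu %||% default_method_menu
  list(values = list(
    n_cells = s$n_cells,
    libsize_mean = format_full(s$libsize_mean),
    libsize_median = format_full(s$libsize_median),
    libsize_cv = format_full(s$libsize_cv),
    zero_fraction = format_full(s$zero_fraction),
    gene_mean_quantiles = paste(format_full(unname(s$gene_mean_quantiles)),
                                collapse = ", "),
    method_menu = paste(menu, collapse = ", ")),
    ctx = list(method_menu = menu))
}

gather_variable_features <- function(ds, opts) {
  flags <- ds$layers$hvg_flags
  if (is.null(flags)) stop("hvg_flags layer required")
  genes <- ds$gene_names[flags]
  n_show <- min(opts$n_hvg_show %||% 100, length(genes))
  list(values = list(n_hvg = length(genes),
                     hvg_genes = paste(genes[seq_len(n_show)],
                                       collapse = ", ")),
       ctx = list(hvg = genes))
}

gather_pcs <- function(ds, opts) {
  v <- variance_explained(ds)
  tab <- paste(sprintf("PC%d: %s (cumulative %s)", seq_along(v$fractions),
                       format_full(v$fractions), format_full(v$cumulative)),
               collapse = "\n")
  list(values = list(variance_table = tab), ctx = list(profile = v))
}

gather_pc_genes <- function(ds, opts) {
  tab <- top_pc_genes(ds, n_pcs = opts$n_pcs %||%
                        min(5, ncol(ds$layers$pc_loadings)),
                      n_genes = opts$n_genes %||% 10)
  block <- vapply(names(tab), function(pc) {
    pos <- paste(sprintf("%s (%s)", tab[[pc]]$positive$gene,
                         format_full(tab[[pc]]$positive$loading)),
                 collapse = ", ")
    neg <- paste(sprintf("%s (%s)", tab[[pc]]$negative$gene,
                         format_full(tab[[pc]]$negative$loading)),
                 collapse = ", ")
    paste0(pc, "\n  positive: ", pos, "\n  negative: ", neg)
  }, character(1))
  list(values = list(pc_gene_table = paste(block, collapse = "\n")),
       ctx = list(table = tab))
}

gather_k <- function(ds, opts) {
  emb <- ds$layers$pc_embedding
  list(values = list(
    n_cells = n_cells(ds),
    n_pcs_used = if (is.null(emb)) opts$n_pcs %||% 10 else ncol(emb),
    clustering_goals = opts$clustering_goals %||%
      "identify the major cell populations"),
    ctx = list())
}

gather_res <- function(ds, opts) {
  list(values = list(
    n_cells = n_cells(ds),
    n_hvg = sum(ds$layers$hvg_flags),
    mean_expression_variability = format_full(expression_variability(ds)),
    median_neighbor_distance = format_full(
      median_neighbor_distance(ds, k = opts$k %||% 20,
                               n_pcs = opts$n_pcs %||% 10))),
    ctx = list())
}

gather_markers <- function(ds, opts) {
  mt <- opts$marker_table
  if (is.null(mt)) stop("analyze_and_annotate needs a marker_table option")
  bundle <- top_markers(mt, n = opts$n_markers %||% 10,
                        max_padj = opts$max_padj %||% 0.05)
  clusters <- ds$layers$cluster_labels
  if (is.null(clusters)) stop("dataset has no cluster_labels layer")
  clusters <- sort(unique(as.character(clusters)))
  block <- vapply(names(bundle), function(cl) {
    sub <- bundle[[cl]]
    paste0("Cluster ", cl, ": ",
           paste(sprintf("%s (log2FC %s)", sub$gene,
                         format_full(sub$avg_log2FC)), collapse = ", "))
  }, character(1))
  list(values = list(marker_block = paste(block, collapse = "\n"),
                     clusters = paste(clusters, collapse = ", ")),
       ctx = list(clusters = clusters))
}

gather_enrichment <- function(ds, opts) {
  tab <- opts$enrichment_table
  if (is.null(tab)) stop("analyze_enrichment needs an enrichment_table option")
  if (nrow(tab) == 0) {
    block <- "No significant enrichment was found at the chosen q-value cutoff."
  } else {
    block <- paste(sprintf("%s: q=%s, overlap %d/%d, genes: %s", tab$set,
                           format_full(tab$q), tab$k, tab$K, tab$genes),
                   collapse = "\n")
  }
  list(values = list(enrichment_block = block), ctx = list(table = tab))
}

gather_network_input <- function(ds, opts) {
  txt <- opts$summary_text
  if (is.null(txt) || !nzchar(txt)) {
    stop("summary_network needs the enrichment summary text")
  }
  list(values = list(summary_text = txt), ctx = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one assistant task end to end
#'
#' Gathers the task's data metrics from the dataset, renders the augmented
#' prompt, submits it to the configured backend, parses the structured
#' payload and returns the full provenance as a RecommendationRecord. On a
#' parser failure the record is returned flagged unparsed with the raw
#' response preserved; metric precondition failures propagate with task
#' context.
#'
#' @param task_id one of [task_ids()]
#' @param ds a CellDataset (run [prepare_layers()] first for tasks needing
#'   derived layers)
#' @param cfg a `BackendConfig`
#' @param experiment_description free-text context injected into the prompt
#' @param opts named list of task options (e.g. `marker_table`,
#'   `enrichment_table`, `clustering_goals`, `k`, `n_pcs`, `method_menu`)
#' @param template_dir optional prompt-template override directory
#' @return a `RecommendationRecord`
#' @export
run_task <- function(task_id, ds, cfg, experiment_description = NULL,
                     opts = list(), template_dir = NULL) {
  reg <- task_registry()
  if (!task_id %in% names(reg)) {
    stop("unknown task id '", task_id, "'; valid: ",
         paste(task_ids(), collapse = ", "))
  }
  spec <- reg[[task_id]]
  gathered <- tryCatch(spec$gather(ds, opts), error = function(e)
    stop("[", task_id, "] ", conditionMessage(e), call. = FALSE))
  tmpl <- get_template(task_id, template_dir)
  prompt <- render_prompt(tmpl, gathered$values, experiment_description)
  resp <- complete(cfg, prompt)
  parsed <- tryCatch(spec$parse(resp$text, gathered$ctx),
                     error = function(e) e)
  ok <- !inherits(parsed, "error")
  recommendation_record(
    task_id = task_id, rendered_prompt = prompt$text,
    raw_response = resp$text,
    parsed_payload = if (ok) parsed else NULL,
    parsed_ok = ok, model_id = resp$model_id, backend_name = cfg$server,
    provenance = list(
      temperature = cfg$temperature,
      prompt_fingerprint = prompt_fingerprint(prompt$text),
      parse_error = if (ok) NULL else conditionMessage(parsed)))
}

#' Enrichment analysis stage: native ORA plus LLM summary
#'
#' Computes the over-representation table natively from the query genes (by
#' default the pooled top markers across clusters), serializes it into the
#' enrichment prompt, and asks the backend for an integrated summary. The
#' table is computed and kept even when the LLM call fails. When no set is
#' significant the prompt says so explicitly rather than seeding the model
#' with an empty table.
#'
#' @param ds CellDataset (universe defaults to all genes detected in >= 1
#'   cell)
#' @param sets GeneSetCollection
#' @param cfg BackendConfig
#' @param query_genes optional explicit gene list; defaults to significant
#'   markers from `opts$marker_table`
#' @param max_q q-value cutoff for reported rows (default 0.05)
#' @param experiment_description,opts,template_dir as in [run_task()]
#' @return list(record = RecommendationRecord, table = EnrichmentTable)
#' @export
analyze_enrichment <- function(ds, sets, cfg, query_genes = NULL,
                               max_q = 0.05, experiment_description = NULL,
                               opts = list(), template_dir = NULL) {
  if (is.null(query_genes)) {
    mt <- opts$marker_table
    if (is.null(mt)) stop("need query_genes or opts$marker_table")
    bundle <- top_markers(mt, n = opts$n_markers %||% 10,
                          max_padj = opts$max_padj %||% 0.05)
    query_genes <- unique(unlist(lapply(bundle, `[[`, "gene")))
  }
  universe <- ds$gene_names[as.numeric(Matrix::colSums(ds$counts > 0)) > 0]
  tab <- run_ora(query_genes, universe, sets, max_q = max_q)
  opts$enrichment_table <- tab
  record <- tryCatch(
    run_task("analyze_enrichment", ds, cfg, experiment_description, opts,
             template_dir),
    error = function(e) {
      warning("LLM summary failed, enrichment table kept: ",
              conditionMessage(e))
      NULL
    })
  list(record = record, table = tab)
}

#' Second-round network extraction and interactive visualization
#'
#' Feeds the enrichment summary back to the LLM with an edge-list wire
#' format ("source|relation|target" lines), parses the edges into a directed
#' igraph, and writes a self-contained interactive HTML visualization.
#'
#' @param enrichment_record RecommendationRecord from the enrichment stage
#'   (its summary text is the second-round input)
#' @param cfg BackendConfig
#' @param html_path optional output path for the HTML file
#' @param template_dir optional template override directory
#' @return list(graph = igraph, edges = data.frame, html = path or NULL)
#' @export
summary_network <- function(enrichment_record, cfg, html_path = NULL,
                            template_dir = NULL) {
  stopifnot(inherits(enrichment_record, "RecommendationRecord"))
  txt <- enrichment_record$raw_response
  record <- run_task("summary_network", ds = NULL, cfg = cfg,
                     opts = list(summary_text = txt),
                     template_dir = template_dir)
  if (!record$parsed_ok) {
    stop("network extraction failed: ", record$provenance$parse_error)
  }
  edges <- record$parsed_payload
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "relation")], directed = TRUE)
  if (!is.null(html_path)) {
    write_network_html(edges, html_path)
  }
  list(graph = g, edges = edges, record = record,
       html = html_path)
}

#' Annotate clusters with predicted cell types
#'
#' Runs the annotation task and, when `apply = TRUE`, writes the predicted
#' labels back to the dataset as a `cell_type_labels` metadata column via
#' [attach_labels()]. Write-back is atomic: any parser error aborts before
#' the dataset is touched.
#'
#' @param ds CellDataset with cluster labels
#' @param marker_table marker data.frame (cluster, gene, avg_log2FC,
#'   p_val_adj)
#' @param cfg BackendConfig
#' @param apply write labels back to the dataset (default FALSE)
#' @param experiment_description,opts,template_dir as in [run_task()]
#' @return list(record = RecommendationRecord, ds = dataset — modified only
#'   when apply succeeded)
#' @export
analyze_and_annotate <- function(ds, marker_table, cfg, apply = FALSE,
                                 experiment_description = NULL,
                                 opts = list(), template_dir = NULL) {
  opts$marker_table <- marker_table
  record <- run_task("analyze_and_annotate", ds, cfg,
                     experiment_description, opts, template_dir)
  if (apply) {
    if (!record$parsed_ok) {
      warning("annotation parse failed; dataset left unchanged")
      return(list(record = record, ds = ds))
    }
    ann <- record$parsed_payload
    mapping <- stats::setNames(ann$label, ann$cluster)
    ds <- attach_labels(ds, "cell_type_labels", mapping, overwrite = TRUE)
  }
  list(record = record, ds = ds)
}

#' Write a self-contained interactive HTML network view
#'
#' Inline data, styles and script (canvas force layout with draggable
#' nodes); no external resources, so the file opens offline.
#'
#' @param edges data.frame(source, relation, target)
#' @param path output HTML file
#' @return path invisibly
#' @export
write_network_html <- function(edges, path) {
  nodes <- unique(c(edges$source, edges$target))
  payload <- jsonlite::toJSON(list(
    nodes = nodes,
    links = data.frame(s = match(edges$source, nodes) - 1L,
                       t = match(edges$target, nodes) - 1L,
                       r = edges$relation)), auto_unbox = FALSE)
  html <- paste0(
"<!DOCTYPE html><html><head><meta charset='utf-8'>
<style>body{font-family:sans-serif;margin:0}canvas{display:block}</style>
</head><body><canvas id='c'></canvas><script>
var data=", payload, ";
var cv=document.getElementById('c'),cx=cv.getContext('2d');
cv.width=innerWidth;cv.height=innerHeight;
var N=data.nodes.length,px=[],py=[],vx=[],vy=[];
for(var i=0;i<N;i++){var a=2*Math.PI*i/N;
px.push(cv.width/2+200*Math.cos(a));py.push(cv.height/2+200*Math.sin(a));
vx.push(0);vy.push(0);}
function step(){for(var i=0;i<N;i++)for(var j=i+1;j<N;j++){
var dx=px[j]-px[i],dy=py[j]-py[i],d2=dx*dx+dy*dy+1,f=4000/d2;
var d=Math.sqrt(d2);vx[i]-=f*dx/d;vy[i]-=f*dy/d;vx[j]+=f*dx/d;vy[j]+=f*dy/d;}
data.links.forEach(function(l){var dx=px[l.t]-px[l.s],dy=py[l.t]-py[l.s];
var d=Math.sqrt(dx*dx+dy*dy)+1,f=0.01*(d-120);
vx[l.s]+=f*dx/d;vy[l.s]+=f*dy/d;vx[l.t]-=f*dx/d;vy[l.t]-=f*dy/d;});
for(var i=0;i<N;i++){vx[i]*=0.85;vy[i]*=0.85;px[i]+=vx[i];py[i]+=vy[i];}}
var drag=-1;
cv.onmousedown=function(e){for(var i=0;i<N;i++){
if(Math.hypot(e.offsetX-px[i],e.offsetY-py[i])<14){drag=i;break;}}};
cv.onmousemove=function(e){if(drag>=0){px[drag]=e.offsetX;py[drag]=e.offsetY;}};
cv.onmouseup=function(){drag=-1;};
function draw(){step();cx.clearRect(0,0,cv.width,cv.height);
cx.strokeStyle='#999';cx.fillStyle='#555';cx.font='10px sans-serif';
data.links.forEach(function(l){cx.beginPath();cx.moveTo(px[l.s],py[l.s]);
cx.lineTo(px[l.t],py[l.t]);cx.stroke();
cx.fillText(l.r,(px[l.s]+px[l.t])/2,(py[l.s]+py[l.t])/2);});
for(var i=0;i<N;i++){cx.beginPath();cx.fillStyle='#4a90d9';
cx.arc(px[i],py[i],10,0,2*Math.PI);cx.fill();cx.fillStyle='#000';
cx.fillText(data.nodes[i],px[i]+12,py[i]+4);}
requestAnimationFrame(draw);}
draw();
</script></body></html>")
  writeLines(html, path)
  invisible(path)
}
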