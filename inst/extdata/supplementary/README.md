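# Supplementary table drop-in directory

The published per-species supplementary appendices of the original study
are distributed by the journal as XLSX and are not redistributed with
this package. To re-derive the published headline results, export them
to CSV and place them here (or pass explicit paths to
`reproduce_published()`):

* `s1_range_changes.csv` — per-species, per-season proportional loss of
  current range and relative change in range size for each scenario
  (A2, A1B, B2) and period (2050, 2080), plus introduced/marginal
  flags. Canonical columns: `species_id`, `season`
  (`breeding`/`nonbreeding`), `introduced`, `marginal`,
  `loss_<scenario>_<period>`, `change_<scenario>_<period>`. Use the
  `schema_map` argument of `read_species_summaries()` if your export
  uses different column names. Percentages are auto-normalized.
* `s7_conservation_status.csv` — per-species conservation statuses.
  Canonical columns: `species_id`, `iucn` (CR/EN/VU/NT/LC),
  `fed_bcc` (FED/BCC/none), `pif` (numeric score, blank if unranked),
  and optionally `climate_category`.
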