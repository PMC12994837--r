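Summary count tables transcribed from the public tables of a national
study of linked primary-care EHR and census-bureau microdata (5.86M
linked persons). All counts were disclosure-protected at source
(discrete Gaussian noise, rounded to multiples of 10), so derived
percentages can differ from exactly recomputed ones by up to ~0.1
percentage points in small cells. Used by the worked-number
reproduction tests and the acceptance script; the analysis pipeline
itself never reads these files.
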