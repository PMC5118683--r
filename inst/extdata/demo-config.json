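{
  "grid": [100, 100],
  "pixel_size": 250,
  "years": [2001, 2002, 2003, 2004, 2005, 2006, 2007, 2008, 2009, 2010, 2011, 2012, 2013],
  "seed": 42,
  "background": "GRAS",
  "regions": {
    "urban_fringe": { "rows": [11, 50], "cols": [11, 50], "initial": "AGRI" },
    "reclamation":  { "rows": [61, 100], "cols": [11, 50], "initial": "GRAS" },
    "succession":   { "rows": [61, 100], "cols": [61, 100], "initial": "CLSH" }
  },
  "patches": [
    { "rows": [26, 34], "cols": [26, 34], "class": "URBN" },
    { "rows": [76, 84], "cols": [76, 84], "class": "DNLE" }
  ],
  "transitions": [
    { "region": "urban_fringe", "from": "AGRI", "to": "URBN", "annual_rate": 0.010, "spatial_mode": "clustered" },
    { "region": "reclamation",  "from": "GRAS", "to": "AGRI", "annual_rate": 0.012, "spatial_mode": "random" },
    { "region": "succession",   "from": "CLSH", "to": "DNLE", "annual_rate": 0.015, "spatial_mode": "clustered" }
  ],
  "noise": { "rate": 0.05 },
  "trend": { "block_size": 10, "interval": 13, "alpha": 0.1 }
}
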