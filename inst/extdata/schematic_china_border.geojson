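{
  "type": "FeatureCollection",
  "note": "Synthetic, heavily simplified schematic of a mainland-China-like study border for demos and examples. Not a cartographic product; do not use for real analyses.",
  "features": [
    {
      "type": "Feature",
      "properties": {"name": "schematic_border", "synthetic": true},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[
          [80, 45], [87, 49], [97, 43], [110, 43], [117, 41], [122, 40],
          [127, 42], [131, 45], [134, 48], [131, 43], [124, 40], [122, 37],
          [120, 35], [122, 31], [120, 28], [117, 24], [112, 21], [108, 21],
          [106, 22], [102, 22], [98, 24], [97, 28], [92, 27], [89, 28],
          [85, 28], [80, 31], [75, 34], [74, 37], [76, 41], [80, 45]
        ]]
      }
    }
  ]
}
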