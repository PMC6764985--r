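{
  "type": "FeatureCollection",
  "note": "Simplified lon/lat box approximations of Southern Ocean management areas for residency summaries; true boundaries are external shapefiles. Swap in any GeoJSON with the same name/category properties for exact geometry.",
  "features": [
    {
      "type": "Feature",
      "properties": {"name": "58.5.1 Kerguelen", "category": "CCAMLR"},
      "geometry": {"type": "Polygon", "coordinates": [[[63, -58], [80, -58], [80, -45], [63, -45], [63, -58]]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "58.4.3b Banzare", "category": "CCAMLR"},
      "geometry": {"type": "Polygon", "coordinates": [[[55, -64], [80, -64], [80, -58], [55, -58], [55, -64]]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "58.4.1 East Antarctic", "category": "CCAMLR"},
      "geometry": {"type": "Polygon", "coordinates": [[[80, -70], [150, -70], [150, -55], [80, -55], [80, -70]]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "58.4.2 Prydz Bay", "category": "CCAMLR"},
      "geometry": {"type": "Polygon", "coordinates": [[[30, -70], [80, -70], [80, -64], [30, -64], [30, -70]]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "IWC Area III", "category": "IWC"},
      "geometry": {"type": "Polygon", "coordinates": [[[0, -75], [70, -75], [70, -20], [0, -20], [0, -75]]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "IWC Area IV", "category": "IWC"},
      "geometry": {"type": "Polygon", "coordinates": [[[70, -75], [130, -75], [130, -20], [70, -20], [70, -75]]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "IWC Area V", "category": "IWC"},
      "geometry": {"type": "Polygon", "coordinates": [[[130, -75], [170, -75], [170, -20], [130, -20], [130, -75]]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "Drygalski MPA", "category": "MPA"},
      "geometry": {"type": "Polygon", "coordinates": [[[63, -67], [88, -67], [88, -60], [63, -60], [63, -67]]]}
    }
  ]
}
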