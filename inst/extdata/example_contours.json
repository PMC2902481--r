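{"regions": [
  {"name": "level_1B_left",
   "slices": [
     {"z": 120.0, "polygons": [[[58.0, 50.0], [80.0, 50.0], [80.0, 72.0], [58.0, 72.0]]]},
     {"z": 122.0, "polygons": [[[56.0, 48.0], [82.0, 48.0], [82.0, 74.0], [56.0, 74.0]]]},
     {"z": 124.0, "polygons": [[[58.0, 50.0], [80.0, 50.0], [80.0, 72.0], [58.0, 72.0]]]}
   ]},
  {"name": "level_2_left",
   "slices": [
     {"z": 104.0, "polygons": [[[48.0, 66.0], [72.0, 66.0], [72.0, 94.0], [48.0, 94.0]]]},
     {"z": 106.0, "polygons": [[[46.0, 64.0], [74.0, 64.0], [74.0, 96.0], [46.0, 96.0]]]}
   ]}
]}
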