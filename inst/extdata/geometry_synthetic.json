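[
  {
    "name": "asc_aorta_1",
    "parent": "heart",
    "length_cm": 2,
    "areas_cm2": [5.3, 5.4433, 5.5411, 5.5623, 5.5003, 5.3747, 5.2253, 5.0997, 5.0377, 5.0589, 5.1567, 5.3],
    "device_site": true
  },
  {
    "name": "asc_aorta_2",
    "parent": "asc_aorta_1",
    "length_cm": 3,
    "areas_cm2": [5.1, 5.2379, 5.332, 5.3524, 5.2927, 5.1718, 5.0282, 4.9073, 4.8476, 4.868, 4.9621, 5.1]
  },
  {
    "name": "coronary_trunk",
    "parent": "heart",
    "length_cm": 1,
    "areas_cm2": [0.12, 0.1232, 0.1255, 0.1259, 0.1245, 0.1217, 0.1183, 0.1155, 0.1141, 0.1145, 0.1168, 0.12],
    "outlet": "coronaries"
  },
  {
    "name": "brachiocephalic",
    "parent": "asc_aorta_2",
    "length_cm": 3.5,
    "areas_cm2": [1.5, 1.5405, 1.5682, 1.5742, 1.5567, 1.5211, 1.4789, 1.4433, 1.4258, 1.4318, 1.4595, 1.5]
  },
  {
    "name": "r_subclavian",
    "parent": "brachiocephalic",
    "length_cm": 4,
    "areas_cm2": [0.6, 0.6162, 0.6273, 0.6297, 0.6227, 0.6085, 0.5915, 0.5773, 0.5703, 0.5727, 0.5838, 0.6],
    "outlet": "right_subclavian"
  },
  {
    "name": "r_carotid",
    "parent": "brachiocephalic",
    "length_cm": 4,
    "areas_cm2": [0.5, 0.5135, 0.5227, 0.5247, 0.5189, 0.507, 0.493, 0.4811, 0.4753, 0.4773, 0.4865, 0.5],
    "outlet": "right_carotid"
  },
  {
    "name": "aortic_arch",
    "parent": "asc_aorta_2",
    "length_cm": 2.5,
    "areas_cm2": [4.6, 4.7243, 4.8092, 4.8277, 4.7738, 4.6648, 4.5352, 4.4262, 4.3723, 4.3908, 4.4757, 4.6]
  },
  {
    "name": "l_carotid",
    "parent": "aortic_arch",
    "length_cm": 4,
    "areas_cm2": [0.5, 0.5135, 0.5227, 0.5247, 0.5189, 0.507, 0.493, 0.4811, 0.4753, 0.4773, 0.4865, 0.5],
    "outlet": "left_carotid"
  },
  {
    "name": "l_subclavian",
    "parent": "aortic_arch",
    "length_cm": 4,
    "areas_cm2": [0.6, 0.6162, 0.6273, 0.6297, 0.6227, 0.6085, 0.5915, 0.5773, 0.5703, 0.5727, 0.5838, 0.6],
    "outlet": "left_subclavian"
  },
  {
    "name": "desc_aorta",
    "parent": "aortic_arch",
    "length_cm": 20,
    "areas_cm2": [3.5, 3.5946, 3.6592, 3.6732, 3.6323, 3.5493, 3.4507, 3.3677, 3.3268, 3.3408, 3.4054, 3.5],
    "outlet": "descending_aorta"
  }
]
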